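# Coverage-aware, relatedness-deduplicated allele frequencies.
#
# AF = AC / AN. AN counts two alleles for every AF-eligible individual
# whose panel covers the variant position (single-sample VCFs carry no
# per-site depth for non-carriers, so the panel BED is the coverage
# criterion). Eligibility keeps exactly one representative per
# relatedness cluster: the sample with the widest merged panel, ties
# broken by earliest submission order. Frequencies can be stratified by
# any combination of metadata fields; an "all" stratum is always
# emitted.

#' Choose one representative per relatedness cluster
#'
#' @param profiles list of `sample_profile` (inserted samples).
#' @param clusters named integer vector (see [relatedness_clusters()]).
#' @return character vector of AF-eligible sample ids.
#' @export
cluster_representatives <- function(profiles, clusters) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  names(profiles) <- ids
  width <- vapply(profiles, function(p)
    sum(BiocGenerics::width(p$panel)), numeric(1))
  ord <- vapply(profiles, function(p) p$submission_order, integer(1))
  members <- split(names(clusters), clusters)
  vapply(members, function(mem) {
    mem[order(-width[mem], ord[mem], mem)][1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Allele number at a position
#'
#' `AN = 2 *` number of AF-eligible individuals whose panel covers the
#' position. Depends only on coverage and eligibility, never on carrier
#' status.
#'
#' @param chrom,pos variant position.
#' @param profiles list of `sample_profile`.
#' @param eligible character vector of AF-eligible sample ids.
#' @return integer AN.
#' @export
allele_number <- function(chrom, pos, profiles, eligible) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  covered <- vapply(profiles[ids %in% eligible], function(p)
    in_panel(chrom, pos, p$panel), logical(1))
  2L * sum(covered)
}

#' Allele count of a variant
#'
#' Heterozygous carriers contribute 1 copy, homozygous-alternate
#' carriers 2, over AF-eligible individuals only.
#'
#' @param key canonical variant key.
#' @param profiles list of `sample_profile`.
#' @param eligible character vector of AF-eligible sample ids.
#' @return integer AC.
#' @export
allele_count <- function(key, profiles, eligible) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  sum(vapply(profiles[ids %in% eligible], function(p) {
    i <- match(key, p$variants$key)
    if (is.na(i)) 0L else p$variants$alt_copies[i]
  }, integer(1)))
}

#' Stratified allele-frequency table
#'
#' One row per (variant, stratum). Strata are formed by every requested
#' combination of metadata fields; the overall `"all"` stratum is always
#' emitted. AF is `NA` when `AN = 0`. Diploid AN is used everywhere,
#' including sex chromosomes; chrX/Y rows carry `diploid_an_flag = TRUE`
#' as a limitation marker.
#'
#' @param profiles list of `sample_profile` (inserted samples).
#' @param clusters named integer vector from [relatedness_clusters()];
#'   pass `NULL` to treat all samples as unrelated.
#' @param metadata data.frame with a `sample` column plus any metadata
#'   fields (sex, suspicion, lab, panel, platform, aligner, caller, ...).
#' @param strata character vector of metadata field names to stratify
#'   by, e.g. `c("sex", "suspicion")`; `NULL` for the overall stratum
#'   only.
#' @return `data.table` with columns `key`, `chrom`, `pos`, `stratum`,
#'   `AC`, `AN`, `AF`, `diploid_an_flag`.
#' @export
af_aggregate <- function(profiles, clusters, metadata, strata = NULL) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  names(profiles) <- ids
  if (is.null(clusters)) {
    clusters <- seq_along(ids)
    names(clusters) <- ids
  }
  eligible <- cluster_representatives(profiles, clusters)
  md <- data.table::as.data.table(metadata)
  if (!"sample" %in% names(md)) .stopf("metadata must have a 'sample' column")
  bad <- setdiff(strata, names(md))
  if (length(bad))
    .stopf("unknown stratum field(s): %s", paste(bad, collapse = ", "))

  # distinct variants across eligible samples
  vars <- data.table::rbindlist(lapply(profiles[eligible], function(p)
    p$variants[, c("chrom", "pos", "key")]))
  vars <- unique(vars, by = "key")
  if (nrow(vars) == 0L)
    return(.dtab(key = character(), chrom = character(),
                                  pos = integer(), stratum = character(),
                                  AC = integer(), AN = integer(),
                                  AF = numeric(), diploid_an_flag = logical()))

  groups <- list(all = eligible)
  if (!is.null(strata)) {
    md_el <- md[md$sample %in% eligible]
    combo <- do.call(paste, c(lapply(strata, function(f) md_el[[f]]),
                              list(sep = "/")))
    for (lev in unique(combo))
      groups[[lev]] <- md_el$sample[combo == lev]
  }
  # coverage and carried-copy matrices over eligible samples (vectorized
  # equivalent of allele_number()/allele_count() per variant)
  cov <- vapply(profiles[eligible], function(p)
    in_panel(vars$chrom, vars$pos, p$panel), logical(nrow(vars)))
  cop <- vapply(profiles[eligible], function(p) {
    i <- match(vars$key, p$variants$key)
    out <- p$variants$alt_copies[i]
    out[is.na(out)] <- 0L
    out
  }, integer(nrow(vars)))
  cov <- matrix(cov, nrow = nrow(vars), dimnames = list(NULL, eligible))
  cop <- matrix(cop, nrow = nrow(vars), dimnames = list(NULL, eligible))

  out <- list()
  for (g in names(groups)) {
    gsam <- groups[[g]]
    an <- as.integer(2L * rowSums(cov[, gsam, drop = FALSE]))
    ac <- as.integer(rowSums(cop[, gsam, drop = FALSE]))
    out[[g]] <- .dtab(
      key = vars$key, chrom = vars$chrom, pos = vars$pos, stratum = g,
      AC = ac, AN = an, AF = ifelse(an == 0L, NA_real_, ac / an),
      diploid_an_flag = grepl("^(chr)?[XY]$", vars$chrom))
  }
  data.table::rbindlist(out)
}

#' Depth and allele-balance histograms per variant
#'
#' Binned carrier counts backing the variant-details histograms.
#'
#' @param records QC-passed call records (with `depth` and `ab`).
#' @param depth_bin depth bin width in reads (default 10).
#' @param ab_bin allele-balance bin width (default 0.05).
#' @return list of two data.tables `depth` (`key`, `bin_lo`, `n`) and
#'   `ab` (`key`, `bin_lo`, `n`).
#' @export
af_histograms <- function(records, depth_bin = 10, ab_bin = 0.05) {
  r <- data.table::as.data.table(records)
  if ("keep" %in% names(r)) r <- r[r$keep == TRUE]
  r[, "key" := paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")]
  dep <- r[!is.na(r$depth),
           list(n = .N),
           by = list(key = key, bin_lo = floor(depth / depth_bin) * depth_bin)]
  ab <- r[!is.na(r$ab),
          list(n = .N),
          by = list(key = key, bin_lo = floor(ab / ab_bin) * ab_bin)]
  list(depth = dep[order(key, bin_lo)], ab = ab[order(key, bin_lo)])
}

#' Write a stratified AF table as a sites-only VCF
#'
#' INFO carries `AC`, `AN`, `AF` from the `"all"` stratum plus
#' `AC_<stratum>` / `AN_<stratum>` / `AF_<stratum>` tags per additional
#' stratum (gnomAD-style).
#'
#' @param af output of [af_aggregate()]. Must include REF/ALT encoded in
#'   the key (`chrom:pos:ref:alt`).
#' @param path output VCF file.
#' @return `path`, invisibly.
#' @export
write_af_vcf <- function(af, path) {
  af <- data.table::as.data.table(af)
  parts <- data.table::tstrsplit(af$key, ":", fixed = TRUE)
  af[, c(".ref", ".alt") := list(parts[[3]], parts[[4]])]
  strata <- setdiff(unique(af$stratum), "all")
  tag <- function(s) gsub("[^A-Za-z0-9]", "_", s)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=varconcord-afreq",
           '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alternate allele count">',
           '##INFO=<ID=AN,Number=1,Type=Integer,Description="Allele number">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Allele frequency">')
  for (s in strata)
    hdr <- c(hdr, sprintf('##INFO=<ID=%s_%s,Number=1,Type=%s,Description="%s in stratum %s">',
                          c("AC", "AN", "AF"), tag(s),
                          c("Integer", "Integer", "Float"),
                          c("Allele count", "Allele number", "Allele frequency"), s))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  base <- af[af$stratum == "all"]
  data.table::setorder(base, chrom, pos)
  info <- vapply(seq_len(nrow(base)), function(i) {
    k <- base$key[i]
    f <- sprintf("AC=%d;AN=%d;AF=%s", base$AC[i], base$AN[i],
                 ifelse(is.na(base$AF[i]), ".", format(base$AF[i], digits = 6)))
    for (s in strata) {
      row <- af[af$key == k & af$stratum == s]
      if (nrow(row) == 1L)
        f <- paste0(f, sprintf(";AC_%s=%d;AN_%s=%d;AF_%s=%s",
                               tag(s), row$AC, tag(s), row$AN, tag(s),
                               ifelse(is.na(row$AF), ".",
                                      format(row$AF, digits = 6))))
    }
    f
  }, character(1))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  base$chrom, base$pos, base$.ref, base$.alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
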