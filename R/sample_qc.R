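# Cohort-level sample tests: noisy, empty, duplicated and kinship.
#
# Noisy/empty samples are detected with Tukey's fences on the per-sample
# variant-count distribution (upper k = 5, lower k = 4). Two samples are
# duplicates when the mean of p1 and p2 exceeds 0.9, where p1 is the
# fraction of sample-1 variants also called in sample 2 (and conversely).
# Kinship uses the robust pairwise relatedness estimator (cutoff 0.25).
# All pairwise tests are computed over the intersection of the two
# samples' panel regions, since panels may differ between laboratories.
# Noisy, empty and duplicated samples are not inserted; kin-related
# samples are inserted but de-duplicated for allele frequencies.

#' Build a sample profile
#'
#' @param sample_id sample identifier.
#' @param records QC-passed call records for this sample (rows of
#'   [filter_records()] output with `keep == TRUE`).
#' @param panel the sample's panel regions (`GRanges`).
#' @param submission_order integer rank used for deterministic
#'   tie-breaking (which duplicate is rejected, cluster representative).
#' @return an object of class `sample_profile` with elements `sample_id`,
#'   `variants` (data.table: chrom, pos, key, alt_copies), `panel`,
#'   `submission_order`.
#' @export
sample_profile <- function(sample_id, records, panel, submission_order = 1L) {
  r <- data.table::as.data.table(records)
  if ("keep" %in% names(r)) r <- r[r$keep == TRUE]
  v <- if (nrow(r)) .dtab(
    chrom = r$chrom, pos = r$pos,
    key = paste(r$chrom, r$pos, r$ref, r$alt, sep = ":"),
    alt_copies = r$alt_copies)
  else .dtab(chrom = character(), pos = integer(),
             key = character(), alt_copies = integer())
  structure(list(sample_id = sample_id, variants = v, panel = panel,
                 submission_order = as.integer(submission_order)),
            class = "sample_profile")
}

#' Tukey's fences on variant counts
#'
#' `lower = Q1 - k_lower * IQR`, `upper = Q3 + k_upper * IQR`, with
#' quartiles computed by linear interpolation between order statistics
#' (`stats::quantile` type 7). The asymmetric defaults follow the
#' database's QC design: a laxer upper fence (k = 5) for noisy samples
#' and k = 4 for empty samples.
#'
#' @param counts per-sample variant counts.
#' @param k_lower,k_upper fence multipliers.
#' @return list with `lower`, `upper`, `q1`, `q3`, `iqr`.
#' @export
tukey_bounds <- function(counts, k_lower = 4, k_upper = 5) {
  if (length(counts) < 4L)
    .stopf("cohort too small for Tukey's fences (%d samples, need >= 4)",
           length(counts))
  q <- stats::quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  list(lower = q[1] - k_lower * iqr, upper = q[2] + k_upper * iqr,
       q1 = q[1], q3 = q[2], iqr = iqr)
}

#' Detect noisy and empty samples
#'
#' A sample is noisy iff its variant count is strictly above the upper
#' fence, empty iff strictly below the lower fence.
#'
#' @param profiles list of `sample_profile`.
#' @param k_lower,k_upper fence multipliers (see [tukey_bounds()]).
#' @return `data.table` with `sample`, `n_variants`, `verdict`
#'   (`"ok"`, `"noisy"`, `"empty"`).
#' @export
detect_noisy_empty <- function(profiles, k_lower = 4, k_upper = 5) {
  counts <- vapply(profiles, function(p) nrow(p$variants), integer(1))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  b <- tukey_bounds(counts, k_lower, k_upper)
  verdict <- ifelse(counts > b$upper, "noisy",
                    ifelse(counts < b$lower, "empty", "ok"))
  data.table::data.table(sample = ids, n_variants = counts, verdict = verdict)
}

# variant keys of a profile restricted to a region
.keys_in_region <- function(p, region) {
  if (nrow(p$variants) == 0L) return(character())
  p$variants$key[in_panel(p$variants$chrom, p$variants$pos, region)]
}

#' Duplicate score of two samples
#'
#' Presence-based (genotype-agnostic) call sharing over the intersection
#' of the two panels. The pair is a duplicate iff
#' `score = (p1 + p2) / 2 > 0.9` (strict).
#'
#' @param a,b `sample_profile` objects.
#' @return list with `p1`, `p2`, `score`, `duplicate` (logical), or all
#'   `NA` (with a warning) when the panel intersection is empty or
#'   either sample has no calls inside it.
#' @export
duplicate_score <- function(a, b) {
  region <- suppressWarnings(GenomicRanges::intersect(a$panel, b$panel))
  na_out <- list(p1 = NA_real_, p2 = NA_real_, score = NA_real_,
                 duplicate = NA)
  if (length(region) == 0L || sum(BiocGenerics::width(region)) == 0L) {
    warning(sprintf("empty panel intersection for %s / %s; duplicate test skipped",
                    a$sample_id, b$sample_id))
    return(na_out)
  }
  ka <- .keys_in_region(a, region)
  kb <- .keys_in_region(b, region)
  if (length(ka) == 0L || length(kb) == 0L) {
    warning(sprintf("no calls in shared regions for %s / %s; duplicate test skipped",
                    a$sample_id, b$sample_id))
    return(na_out)
  }
  p1 <- mean(ka %in% kb)
  p2 <- mean(kb %in% ka)
  score <- (p1 + p2) / 2
  list(p1 = p1, p2 = p2, score = score, duplicate = score > 0.9)
}

#' Pairwise kinship coefficient
#'
#' Robust between-sample relatedness estimator
#' `phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(a) + N_Aa(b))`, where
#' `N_Aa,Aa` counts sites heterozygous in both samples, `N_AA,aa` counts
#' opposite-homozygote sites and `N_Aa(.)` counts heterozygous sites per
#' sample. Computed over the union of called sites inside the panel
#' intersection; positions not called in a sample are taken as
#' homozygous reference. A pair is related iff `phi >= 0.25`.
#'
#' @param a,b `sample_profile` objects.
#' @return list with `phi`, `n_shared_sites` (sites entering the
#'   estimator), `related`; `phi` is `NA` (pair skipped) when neither
#'   sample has a heterozygous site in the shared regions.
#' @export
kinship <- function(a, b) {
  region <- suppressWarnings(GenomicRanges::intersect(a$panel, b$panel))
  if (length(region) == 0L || sum(BiocGenerics::width(region)) == 0L)
    return(list(phi = NA_real_, n_shared_sites = 0L, related = NA))
  va <- a$variants[in_panel(a$variants$chrom, a$variants$pos, region)]
  vb <- b$variants[in_panel(b$variants$chrom, b$variants$pos, region)]
  keys <- union(va$key, vb$key)
  ga <- va$alt_copies[match(keys, va$key)]; ga[is.na(ga)] <- 0L
  gb <- vb$alt_copies[match(keys, vb$key)]; gb[is.na(gb)] <- 0L
  n_het_a <- sum(ga == 1L)
  n_het_b <- sum(gb == 1L)
  if (n_het_a + n_het_b == 0L)
    return(list(phi = NA_real_, n_shared_sites = length(keys), related = NA))
  n_hethet <- sum(ga == 1L & gb == 1L)
  n_opp <- sum((ga == 2L & gb == 0L) | (ga == 0L & gb == 2L))
  phi <- (n_hethet - 2 * n_opp) / (n_het_a + n_het_b)
  list(phi = phi, n_shared_sites = length(keys), related = phi >= 0.25)
}

#' Run all pairwise sample tests
#'
#' @param profiles list of `sample_profile`.
#' @return list with `duplicates` and `kinship` data.tables
#'   (one row per pair).
#' @export
pairwise_sample_tests <- function(profiles) {
  n <- length(profiles)
  # panel signatures: pairs sharing an identical panel skip the interval
  # intersection (records are already restricted to their own panel)
  sig <- vapply(profiles, function(p)
    paste(as.character(GenomeInfoDb::seqnames(p$panel)),
          BiocGenerics::start(p$panel), BiocGenerics::end(p$panel),
          collapse = ";"), character(1))
  dup <- list(); kin <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    a <- profiles[[i]]; b <- profiles[[j]]
    if (sig[i] == sig[j]) {
      ka <- a$variants$key; kb <- b$variants$key
      if (length(ka) && length(kb)) {
        p1 <- mean(ka %in% kb); p2 <- mean(kb %in% ka)
        score <- (p1 + p2) / 2
        d <- list(p1 = p1, p2 = p2, score = score, duplicate = score > 0.9)
      } else d <- list(p1 = NA_real_, p2 = NA_real_, score = NA_real_,
                       duplicate = NA)
      keys <- union(ka, kb)
      ga <- a$variants$alt_copies[match(keys, ka)]; ga[is.na(ga)] <- 0L
      gb <- b$variants$alt_copies[match(keys, kb)]; gb[is.na(gb)] <- 0L
      het <- sum(ga == 1L) + sum(gb == 1L)
      if (het > 0L) {
        phi <- (sum(ga == 1L & gb == 1L) -
                2 * sum((ga == 2L & gb == 0L) | (ga == 0L & gb == 2L))) / het
        k <- list(phi = phi, n_shared_sites = length(keys),
                  related = phi >= 0.25)
      } else k <- list(phi = NA_real_, n_shared_sites = length(keys),
                       related = NA)
    } else {
      d <- suppressWarnings(duplicate_score(a, b))
      k <- kinship(a, b)
    }
    dup[[length(dup) + 1L]] <- data.table::data.table(
      sample1 = a$sample_id, sample2 = b$sample_id,
      p1 = d$p1, p2 = d$p2, score = d$score, duplicate = d$duplicate)
    kin[[length(kin) + 1L]] <- data.table::data.table(
      sample1 = a$sample_id, sample2 = b$sample_id,
      phi = k$phi, n_shared_sites = k$n_shared_sites, related = k$related)
  }
  list(duplicates = data.table::rbindlist(dup),
       kinship = data.table::rbindlist(kin))
}

#' Partition samples into relatedness clusters
#'
#' Connected components of the union graph of kinship edges and
#' shared-family edges. One representative per cluster is later eligible
#' for allele-frequency calculation.
#'
#' @param samples character vector of all sample ids.
#' @param kin_pairs data.frame with `sample1`, `sample2` for pairs
#'   declared related (e.g. rows of [pairwise_sample_tests()]'s kinship
#'   table with `related == TRUE`).
#' @param family_ids optional named character vector mapping sample id ->
#'   family id (`NA`/missing means no family).
#' @return named integer vector: cluster membership per sample.
#' @export
relatedness_clusters <- function(samples, kin_pairs = NULL, family_ids = NULL) {
  edges <- character(0)
  if (!is.null(kin_pairs) && nrow(kin_pairs) > 0L)
    edges <- c(edges, rbind(kin_pairs$sample1, kin_pairs$sample2))
  if (!is.null(family_ids)) {
    fam <- family_ids[!is.na(family_ids) & nzchar(family_ids)]
    for (f in unique(fam)) {
      mem <- names(fam)[fam == f]
      if (length(mem) > 1L)
        edges <- c(edges, rbind(mem[-length(mem)], mem[-1L]))
    }
  }
  g <- igraph::graph_from_data_frame(
    d = if (length(edges)) data.frame(from = edges[c(TRUE, FALSE)],
                                      to = edges[c(FALSE, TRUE)])
        else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = samples))
  comp <- igraph::components(g)
  membership <- comp$membership[samples]
  names(membership) <- samples
  membership
}

#' Cohort sample-QC verdicts
#'
#' Runs the noisy/empty, duplicate and kinship tests and combines them
#' into per-sample verdicts: noisy, empty and duplicated samples are
#' excluded from insertion (for a duplicate pair, the later-submitted
#' sample is rejected); kin-related samples are kept but grouped into
#' relatedness clusters for allele-frequency de-duplication.
#'
#' @param profiles list of `sample_profile`.
#' @param family_ids optional named character vector sample -> family.
#' @return list with `verdicts` (data.table: sample, n_variants,
#'   verdict, insert), `pairs` (pairwise test tables) and `clusters`
#'   (membership vector over inserted samples).
#' @export
sample_qc <- function(profiles, family_ids = NULL) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  ne <- detect_noisy_empty(profiles)
  pairs <- pairwise_sample_tests(profiles)
  verdict <- ne$verdict
  names(verdict) <- ne$sample
  ord <- vapply(profiles, function(p) p$submission_order, integer(1))
  names(ord) <- ids
  dups <- pairs$duplicates[pairs$duplicates$duplicate %in% TRUE]
  if (nrow(dups)) for (i in seq_len(nrow(dups))) {
    s1 <- dups$sample1[i]; s2 <- dups$sample2[i]
    later <- if (ord[[s2]] >= ord[[s1]]) s2 else s1
    if (verdict[[later]] == "ok") verdict[[later]] <- "duplicate"
  }
  insert <- verdict == "ok"
  kin_rel <- pairs$kinship[pairs$kinship$related %in% TRUE]
  kin_rel <- kin_rel[kin_rel$sample1 %in% ids[insert] &
                     kin_rel$sample2 %in% ids[insert]]
  fam <- NULL
  if (!is.null(family_ids)) {
    fam <- family_ids[match(ids[insert], names(family_ids))]
    names(fam) <- ids[insert]
  }
  clusters <- relatedness_clusters(ids[insert], kin_rel, fam)
  list(verdicts = data.table::data.table(sample = ne$sample,
                                         n_variants = ne$n_variants,
                                         verdict = unname(verdict[ne$sample]),
                                         insert = unname(insert[ne$sample])),
       pairs = pairs, clusters = clusters)
}
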