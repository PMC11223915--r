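# Record-level hard filters applied to each VCF call before ingestion.
#
# A record is dropped iff any of: FILTER different from PASS (an unset
# "." FILTER is treated as non-PASS), homozygous-reference or missing
# genotype, allele balance below 0.2, depth below the submitter's
# threshold, or position outside the panel. Boundary semantics are
# strict: AB exactly 0.2 and depth exactly at the threshold pass.

#' Allele balance of a call record
#'
#' Fraction of reads supporting the alternate allele,
#' `alt / (ref + alt)` from the allelic depths. For decomposed
#' multi-allelic sites this is computed per alternate against
#' ref + that alternate.
#'
#' @param ref_depth,alt_depth allelic depths (vectors).
#' @return numeric vector in `[0, 1]`; `NA` when depths are missing or
#'   the denominator is 0.
#' @export
allele_balance <- function(ref_depth, alt_depth) {
  den <- ref_depth + alt_depth
  ifelse(is.na(den) | den == 0L, NA_real_, alt_depth / den)
}

#' Apply record-level hard filters
#'
#' @param records call records as returned by [read_sample_vcf()].
#' @param panel a `GRanges` of panel regions (see [read_panel()]).
#' @param min_depth submitter depth threshold, must be >= 10 (validated
#'   upstream by [validate_metadata()]).
#' @return the records with added columns `ab`, `keep` and `reason`
#'   (first failing test, `NA` when kept). Filtering is
#'   order-independent; reasons are checked in a fixed order:
#'   `non-PASS`, `bad-GT`, `hom-ref`, `no-AB`, `low-AB`, `low-DP`,
#'   `off-panel`.
#' @export
filter_records <- function(records, panel, min_depth) {
  r <- data.table::as.data.table(records)
  min_depth <- as.integer(min_depth)
  if (is.na(min_depth) || min_depth < 10L)
    .stopf("min_depth must be >= 10, got %s", min_depth)
  n <- nrow(r)
  if (n == 0L) {
    r[, c("ab", "keep", "reason") := list(numeric(), logical(), character())]
    return(r[])
  }
  ab <- allele_balance(r$ref_depth, r$alt_depth)
  non_pass <- is.na(r$filter) | r$filter != "PASS"
  bad_gt <- r$malformed_gt
  hom_ref <- !bad_gt & (is.na(r$alt_copies) | r$alt_copies == 0L)
  no_ab <- is.na(ab)
  low_ab <- !no_ab & ab < 0.2
  low_dp <- is.na(r$depth) | r$depth < min_depth
  off_panel <- !in_panel(r$chrom, r$pos, panel)
  reason <- rep(NA_character_, n)
  for (nm in rev(c("non-PASS", "bad-GT", "hom-ref", "no-AB", "low-AB",
                   "low-DP", "off-panel"))) {
    flag <- switch(nm, "non-PASS" = non_pass, "bad-GT" = bad_gt,
                   "hom-ref" = hom_ref, "no-AB" = no_ab, "low-AB" = low_ab,
                   "low-DP" = low_dp, "off-panel" = off_panel)
    reason[flag] <- nm
  }
  r[, "ab" := ab]
  r[, "reason" := reason]
  r[, "keep" := is.na(reason)]
  r[]
}

#' Write a per-sample record-QC report
#'
#' @param records output of [filter_records()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(records, path) {
  cols <- intersect(c("sample", "chrom", "pos", "ref", "alt", "depth",
                      "depth_source", "ab", "keep", "reason"),
                    names(records))
  data.table::fwrite(data.table::as.data.table(records)[, cols, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}
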