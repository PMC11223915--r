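# Classification ledger and tiered concordance models.
#
# The ledger keeps the latest five-tier call per (variant, laboratory),
# selected by classification date (same-date ties: latest in submission
# order, flagged). Concordance is assessed under three nested models:
# five-tier {P}{LP}{VUS}{LB}{B}, three-tier {LP/P}{VUS}{LB/B} and
# two-tier actionable {LP/P} vs non-actionable {VUS/LB/B}; discordance
# across the two-tier boundary is clinically significant.

#' Map five-tier labels to a tier model's groups
#'
#' @param labels character vector of five-tier labels.
#' @param model `"five"`, `"three"` or `"two"`.
#' @return character vector of group names under the model.
#' @export
tier_group <- function(labels, model = c("five", "three", "two")) {
  model <- match.arg(model)
  bad <- setdiff(labels, .FIVE_TIER)
  if (length(bad))
    .stopf("unknown classification label(s): %s", paste(bad, collapse = ", "))
  switch(model,
    five = labels,
    three = c(B = "LB/B", LB = "LB/B", VUS = "VUS",
              LP = "LP/P", P = "LP/P")[labels],
    two = c(B = "non-actionable", LB = "non-actionable",
            VUS = "non-actionable", LP = "actionable",
            P = "actionable")[labels])
}

#' Build the classification ledger
#'
#' @param submissions canonical classification records (e.g.
#'   `records` from [parse_classifications()], possibly concatenated
#'   across labs): columns `key`, `lab`, `classification`, `date`, and
#'   optionally `row_in_file` for same-date tie-breaking plus any
#'   carried columns (`reasoning`, `submitter`, ...).
#' @return `data.table` ledger, one row per (variant, lab), with
#'   `tie_flag` marking entries that won a same-date tie.
#' @export
build_ledger <- function(submissions) {
  s <- data.table::as.data.table(submissions)
  need <- c("key", "lab", "classification", "date")
  miss <- setdiff(need, names(s))
  if (length(miss))
    .stopf("submissions lack column(s): %s", paste(miss, collapse = ", "))
  if (!"row_in_file" %in% names(s)) s$row_in_file <- seq_len(nrow(s))
  data.table::setorder(s, key, lab, date, row_in_file)
  tie <- s[, list(tie_flag = .N > 1L && sum(date == max(date)) > 1L),
           by = list(key, lab)]
  ledger <- s[, .SD[.N], by = list(key, lab)]
  ledger <- merge(ledger, tie, by = c("key", "lab"))
  ledger[]
}

#' Concordance status of one variant
#'
#' @param ledger a ledger from [build_ledger()].
#' @param key variant key.
#' @return list with `key`, `n_labs` and `concordant` (named logical,
#'   per model); models are `NA` for single-lab variants (excluded from
#'   discrepancy analysis).
#' @export
concordance <- function(ledger, key) {
  labels <- ledger$classification[ledger$key == key]
  n <- length(labels)
  if (n < 2L)
    return(list(key = key, n_labs = n,
                concordant = c(five = NA, three = NA, two = NA)))
  conc <- vapply(c("five", "three", "two"), function(m)
    length(unique(tier_group(labels, m))) == 1L, logical(1))
  list(key = key, n_labs = n, concordant = conc)
}

#' Concordance status of all multi-classified variants
#'
#' @param ledger a ledger from [build_ledger()].
#' @return `data.table` with one row per variant classified by at least
#'   two labs: `key`, `n_labs`, `conc_five`, `conc_three`, `conc_two`.
#' @export
concordance_all <- function(ledger) {
  l <- data.table::as.data.table(ledger)
  l[, "g3" := tier_group(l$classification, "three")]
  l[, "g2" := tier_group(l$classification, "two")]
  out <- l[, list(n_labs = .N,
                  conc_five = length(unique(classification)) == 1L,
                  conc_three = length(unique(g3)) == 1L,
                  conc_two = length(unique(g2)) == 1L),
           by = key]
  out[out$n_labs >= 2L]
}

#' Cohort-level concordance summary
#'
#' Counts and one-decimal percentages (half-up rounding) over all
#' multi-classified variants.
#'
#' @param ledger a ledger from [build_ledger()].
#' @return list with `n_classified` (variants with >= 1 lab),
#'   `n_multi`, `n_consensus`, `n_discordant_five`, `n_discordant_three`,
#'   `n_discordant_two` and the corresponding percentages
#'   (`pct_consensus`, `pct_discordant_five`, `pct_discordant_three`,
#'   `pct_discordant_two`) relative to the multi-classified count.
#' @export
cohort_summary <- function(ledger) {
  cc <- concordance_all(ledger)
  n_multi <- nrow(cc)
  n_cons <- sum(cc$conc_five)
  nd5 <- sum(!cc$conc_five)
  nd3 <- sum(!cc$conc_three)
  nd2 <- sum(!cc$conc_two)
  list(n_classified = length(unique(ledger$key)),
       n_multi = n_multi,
       n_consensus = n_cons,
       n_discordant_five = nd5,
       n_discordant_three = nd3,
       n_discordant_two = nd2,
       pct_consensus = pct1(n_cons, n_multi),
       pct_discordant_five = pct1(nd5, n_multi),
       pct_discordant_three = pct1(nd3, n_multi),
       pct_discordant_two = pct1(nd2, n_multi))
}

#' Triggered discrepancy notifications
#'
#' Pure rule-matching contract for the notification feature: given the
#' new ledger entries of a submission and user preference rules, return
#' the (user, variant) pairs to notify. Delivery is out of scope.
#'
#' @param ledger_delta new/updated ledger rows (with `key`, `lab`,
#'   `classification`; a `gene` column is matched against gene lists).
#' @param preferences data.frame of rules: `user`, and optionally
#'   `genes` (comma-separated list), `into_group` (two/three/five-tier
#'   group name that the new classification must fall into).
#' @return `data.table` with `user`, `key`.
#' @export
notification_matches <- function(ledger_delta, preferences) {
  d <- data.table::as.data.table(ledger_delta)
  p <- data.table::as.data.table(preferences)
  out <- list()
  for (i in seq_len(nrow(p))) {
    hits <- rep(TRUE, nrow(d))
    if (!is.null(p$genes) && !is.na(p$genes[i]) && nzchar(p$genes[i])) {
      gl <- trimws(strsplit(p$genes[i], ",")[[1]])
      hits <- hits & !is.na(d$gene) & d$gene %in% gl
    }
    if (!is.null(p$into_group) && !is.na(p$into_group[i]) &&
        nzchar(p$into_group[i])) {
      grp <- p$into_group[i]
      hits <- hits & (d$classification == grp |
                      tier_group(d$classification, "three") == grp |
                      tier_group(d$classification, "two") == grp)
    }
    if (any(hits))
      out[[length(out) + 1L]] <- .dtab(
        user = p$user[i], key = d$key[hits])
  }
  if (length(out) == 0L)
    return(.dtab(user = character(), key = character()))
  unique(data.table::rbindlist(out))
}
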