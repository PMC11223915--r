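# Three-phase discrepancy-resolution planner and revision accounting.
#
# Only variants discordant under the two-tier model (clinically
# significant discrepancies) enter the procedure. Each phase assigns
# laboratories to review their classification; assigned labs resubmit
# and remaining discordance is re-assessed. Phase 1 minimizes workload
# (oldest / outlier / random-of-two / all); Phase 2 has the remaining
# labs review (or the single dissenter after an "all" Phase 1); Phase 3
# moves to discussion: an email group for variants classified by up to
# three labs, a joint meeting for four or more. Phase 1-2 reviews count
# as revisions; Phase 3 discussions do not.

#' Extract two-tier discrepancy cases from a ledger
#'
#' @param ledger a ledger from [build_ledger()].
#' @return list of `discrepancy_case` objects: each a list with `key`
#'   and `labs` (data.table: `lab`, `classification`, `group`, `date`).
#' @export
discrepancy_cases <- function(ledger) {
  cc <- concordance_all(ledger)
  keys <- cc$key[!cc$conc_two]
  l <- data.table::as.data.table(ledger)
  lapply(keys, function(k) {
    d <- l[l$key == k, list(lab, classification, date)]
    d$group <- tier_group(d$classification, "two")
    structure(list(key = k, labs = d), class = "discrepancy_case")
  })
}

.case_groups <- function(case) split(case$labs$lab, case$labs$group)

#' Plan the Phase-1 assignment for a case
#'
#' Two labs: the lab with the oldest classification reviews (`oldest`).
#' More than two labs: a lone lab opposing at least two reviews
#' (`outlier`); else, if one group has exactly two labs and the other at
#' least two, one lab drawn uniformly from that two-lab group
#' (`random-of-two`; when both groups have exactly two labs, the "first"
#' group is the one whose oldest classification is older); else all labs
#' review (`all`).
#'
#' Uses R's RNG for the random-of-two draw: seed upstream.
#'
#' @param case a `discrepancy_case`.
#' @return list with `key`, `phase = 1`, `labs` (assigned), `rule`.
#' @export
plan_phase1 <- function(case) {
  d <- case$labs
  grp <- .case_groups(case)
  if (length(grp) != 2L)
    .stopf("case %s is not two-tier discordant", case$key)
  sizes <- lengths(grp)
  n <- nrow(d)
  if (n == 2L) {
    oldest <- d$lab[order(d$date, d$lab)][1L]
    return(list(key = case$key, phase = 1L, labs = oldest, rule = "oldest"))
  }
  if (min(sizes) == 1L && max(sizes) >= 2L) {
    outlier <- grp[[which.min(sizes)]]
    return(list(key = case$key, phase = 1L, labs = outlier, rule = "outlier"))
  }
  if (min(sizes) == 2L && max(sizes) >= 2L) {
    if (all(sizes == 2L)) {
      # first group = the one holding the older oldest classification
      oldest_by_group <- vapply(grp, function(labs)
        min(d$date[d$lab %in% labs]), numeric(1))
      two_grp <- grp[[which.min(oldest_by_group)]]
    } else {
      two_grp <- grp[[which.min(sizes)]]
    }
    pick <- sample(sort(two_grp), 1L)
    return(list(key = case$key, phase = 1L, labs = pick,
                rule = "random-of-two"))
  }
  list(key = case$key, phase = 1L, labs = sort(d$lab), rule = "all")
}

#' Plan the Phase-2 assignment for a case still discordant after Phase 1
#'
#' After an `oldest`, `outlier` or `random-of-two` Phase 1, the
#' remaining labs review (`remaining`). After an `all` Phase 1 the
#' single dissenting lab carries out a further review
#' (`further-review`); if more than one lab dissents the case is flagged
#' for manual handling (`manual`, with a warning).
#'
#' @param case the case with its current (post-Phase-1) groups.
#' @param phase1 the Phase-1 assignment for this case.
#' @return list with `key`, `phase = 2`, `labs`, `rule`.
#' @export
plan_phase2 <- function(case, phase1) {
  d <- case$labs
  if (phase1$rule %in% c("oldest", "outlier", "random-of-two")) {
    remaining <- sort(setdiff(d$lab, phase1$labs))
    return(list(key = case$key, phase = 2L, labs = remaining,
                rule = "remaining"))
  }
  grp <- .case_groups(case)
  sizes <- lengths(grp)
  minority <- grp[[which.min(sizes)]]
  if (length(minority) == 1L)
    return(list(key = case$key, phase = 2L, labs = minority,
                rule = "further-review"))
  warning(sprintf(
    "case %s: %d labs dissent after an 'all' Phase 1; flagged for manual handling",
    case$key, length(minority)))
  # no assignment is planned: the situation is outside the documented
  # algorithm, and auto-assigning would break the economy guarantee
  list(key = case$key, phase = 2L, labs = character(0), rule = "manual")
}

#' Plan the Phase-3 assignment
#'
#' Up to three classifying labs: an email group; four or more: a joint
#' meeting. All classifying labs take part; these discussions are not
#' counted as revisions.
#'
#' @param case a `discrepancy_case`.
#' @return list with `key`, `phase = 3`, `labs`, `rule`
#'   (`"email-group"` or `"meeting"`).
#' @export
plan_phase3 <- function(case) {
  labs <- sort(case$labs$lab)
  rule <- if (length(labs) <= 3L) "email-group" else "meeting"
  list(key = case$key, phase = 3L, labs = labs, rule = rule)
}

# apply scripted post-review labels for one phase's assignments
.apply_scripts <- function(ledger, assignments, scripts, ph) {
  log <- list()
  l <- data.table::as.data.table(ledger)
  for (a in assignments) {
    for (lb in a$labs) {
      new_label <- NA_character_
      if (!is.null(scripts) && nrow(scripts)) {
        hit <- which(scripts$phase == ph & scripts$key == a$key &
                     scripts$lab == lb)
        if (length(hit)) new_label <- scripts$new_label[hit[1L]]
      }
      idx <- which(l$key == a$key & l$lab == lb)
      old <- l$classification[idx]
      if (is.na(new_label)) new_label <- old   # reaffirmed as-is
      l$classification[idx] <- new_label
      log[[length(log) + 1L]] <- .dtab(
        phase = ph, key = a$key, lab = lb, rule = a$rule,
        old_label = old, outcome = new_label,
        revision = ph <= 2L)
    }
  }
  list(ledger = l, log = data.table::rbindlist(log))
}

#' Execute the three-phase resolution procedure
#'
#' Plans each phase over the currently discordant cases, applies
#' scripted post-review labels (the planner plans; laboratory behaviour
#' is supplied by the script: a lab without a script entry reaffirms its
#' current label), updates the ledger and re-assesses two-tier
#' concordance after each phase.
#'
#' @param ledger a ledger from [build_ledger()].
#' @param scripts data.frame of scripted outcomes: `phase`, `key`,
#'   `lab`, `new_label`.
#' @param seed optional seed for the random-of-two draws.
#' @return list with `log` (all review records; `revision == TRUE` for
#'   Phases 1-2), `cases` (data.table: `key`, `n_labs`,
#'   `resolved_phase` -- `NA` if never resolved), `phase_rules`
#'   (assignment rules used) and `final_ledger`.
#' @export
execute_resolution <- function(ledger, scripts = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(scripts)) scripts <- data.table::as.data.table(scripts)
  cases <- discrepancy_cases(ledger)
  keys0 <- vapply(cases, function(c) c$key, character(1))
  n_labs0 <- vapply(cases, function(c) nrow(c$labs), integer(1))
  resolved_phase <- rep(NA_integer_, length(cases))
  names(resolved_phase) <- keys0
  log <- list()
  rules <- list()
  l <- ledger
  phase1_by_key <- list()
  open_keys <- keys0
  for (phase in 1:3) {
    if (length(open_keys) == 0L) break
    open_cases <- discrepancy_cases(l)
    open_cases <- open_cases[vapply(open_cases, function(c)
      c$key %in% open_keys, logical(1))]
    assignments <- lapply(open_cases, function(case) {
      a <- switch(as.character(phase),
                  "1" = plan_phase1(case),
                  "2" = plan_phase2(case, phase1_by_key[[case$key]]),
                  "3" = plan_phase3(case))
      a
    })
    if (phase == 1L)
      for (a in assignments) phase1_by_key[[a$key]] <- a
    step <- .apply_scripts(l, assignments, scripts, phase)
    l <- step$ledger
    log[[phase]] <- step$log
    rules[[phase]] <- data.table::rbindlist(lapply(assignments, function(a)
      .dtab(phase = phase, key = a$key, rule = a$rule,
                             n_assigned = length(a$labs))))
    still <- concordance_all(l)
    still_keys <- still$key[!still$conc_two]
    newly_resolved <- setdiff(open_keys, still_keys)
    resolved_phase[newly_resolved] <- phase
    open_keys <- intersect(open_keys, still_keys)
  }
  list(log = data.table::rbindlist(log),
       cases = .dtab(key = keys0, n_labs = n_labs0,
                                      resolved_phase = unname(resolved_phase[keys0])),
       phase_rules = data.table::rbindlist(rules),
       final_ledger = l)
}

#' Revision accounting
#'
#' Summarizes an executed resolution: per-phase revision counts (Phase 3
#' discussions are not revisions), per-phase resolved counts and
#' one-decimal percentages (half-up), the overall resolution rate, and
#' the brute-force comparator -- the number of revisions a re-review of
#' every classifying lab of every initially discordant case would have
#' required.
#'
#' @param log revision log from [execute_resolution()].
#' @param cases case table from [execute_resolution()].
#' @return list with `phases` (data.table: `phase`, `n_addressed`,
#'   `revisions`, `resolved`, `pct_resolved`), `total_revisions`,
#'   `n_cases`, `resolved_total`, `pct_resolved_total`, `unresolved`,
#'   `brute_force_revisions`.
#' @export
account <- function(log, cases) {
  log <- data.table::as.data.table(log)
  cases <- data.table::as.data.table(cases)
  phases <- data.table::rbindlist(lapply(1:3, function(ph) {
    addressed <- if (ph == 1L) nrow(cases)
                 else sum(is.na(cases$resolved_phase) |
                          cases$resolved_phase >= ph)
    resolved <- sum(cases$resolved_phase %in% ph)
    revs <- if (nrow(log)) length(unique(
      paste(log$key, log$lab)[log$phase == ph & log$revision])) else 0L
    data.table::data.table(phase = ph, n_addressed = addressed,
                           revisions = revs, resolved = resolved,
                           pct_resolved = pct1(resolved, addressed))
  }))
  resolved_total <- sum(!is.na(cases$resolved_phase))
  list(phases = phases,
       total_revisions = sum(phases$revisions),
       n_cases = nrow(cases),
       resolved_total = resolved_total,
       pct_resolved_total = pct1(resolved_total, nrow(cases)),
       unresolved = nrow(cases) - resolved_total,
       brute_force_revisions = sum(cases$n_labs))
}
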