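# Deterministic synthetic-data generator: every input the pipeline
# consumes can be produced here, byte-reproducible under a fixed seed.
#
# The cohort generator emulates targeted-panel germline calling: one
# single-sample VCF per individual (dialect GT:AD:DP, FILTER PASS unless
# injected), a shared panel BED, an individual-metadata table and
# dataset metadata. Injected pathologies (duplicate, noisy, empty,
# parent-offspring pair) are constructed to be detectable by the
# corresponding sample test. The classification generator emits per-lab
# tables realizing an exact concordance profile, including the dates and
# group splits that drive every branch of the resolution planner, plus
# scripted post-review labels per phase.

#' Generate a reference sequence
#'
#' @param seed RNG seed.
#' @param length sequence length (bases).
#' @param repeat_tracts optional list of tracts to implant, each
#'   `list(pos =, unit =, n =)`: `n` copies of `unit` starting at `pos`.
#' @param chrom chromosome name.
#' @param path optional FASTA output path.
#' @return named character vector of length 1 (the sequence); written to
#'   `path` as FASTA when given.
#' @export
make_reference <- function(seed, length = 10000L, repeat_tracts = NULL,
                           chrom = "1", path = NULL) {
  stopifnot(length > 0L)
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  for (tr in repeat_tracts) {
    tract <- strrep(tr$unit, tr$n)
    end <- tr$pos + nchar(tract) - 1L
    if (tr$pos < 1L || end > length)
      .stopf("repeat tract at %d..%d outside reference", tr$pos, end)
    seq <- paste0(substr(seq, 1, tr$pos - 1L), tract,
                  substr(seq, end + 1L, length))
  }
  out <- stats::setNames(seq, chrom)
  if (!is.null(path)) write_reference(out, path)
  out
}

#' Cohort recipe
#'
#' Stated-world defaults for the synthetic cohort: 20 unrelated
#' individuals plus one parent-offspring pair, one duplicate, one noisy
#' and one empty injection, genotypes at 2000 biallelic panel sites with
#' allele frequency 0.5 (the regime in which the kinship estimator's
#' expectations phi = 0 / 0.25 are exercised).
#'
#' @param seed RNG seed.
#' @param n_unrelated unrelated individuals.
#' @param n_po_pairs parent-offspring pairs (kinship-detectable, no
#'   shared family id).
#' @param n_family_pairs unrelated pairs sharing a family identifier
#'   (family-edge deduplication only).
#' @param n_duplicates duplicate injections (resubmission of an
#'   unrelated sample with a few calls added/dropped).
#' @param n_noisy,n_empty noisy / empty sample injections.
#' @param n_sites biallelic sites in the panel.
#' @param maf per-site alternate allele frequency (scalar or vector).
#' @param depth simulated read depth per call.
#' @param ref_length reference length; the panel covers `[1, ref_length]`.
#' @return list of class `cohort_recipe`.
#' @export
cohort_recipe <- function(seed = 1L, n_unrelated = 20L, n_po_pairs = 1L,
                          n_family_pairs = 1L, n_duplicates = 1L,
                          n_noisy = 1L, n_empty = 1L, n_sites = 2000L,
                          maf = 0.5, depth = 100L, ref_length = 50000L) {
  structure(list(seed = seed, n_unrelated = n_unrelated,
                 n_po_pairs = n_po_pairs, n_family_pairs = n_family_pairs,
                 n_duplicates = n_duplicates, n_noisy = n_noisy,
                 n_empty = n_empty, n_sites = n_sites, maf = maf,
                 depth = depth, ref_length = ref_length),
            class = "cohort_recipe")
}

# calls table for one sample from a genotype vector over sites
.calls_from_gt <- function(sites, gt, depth) {
  idx <- which(gt > 0L)
  if (length(idx) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  gt = character(), ref_depth = integer(),
                                  alt_depth = integer(), depth = integer()))
  g <- gt[idx]
  ad_alt <- ifelse(g == 2L, depth, as.integer(round(depth / 2)))
  data.table::data.table(
    chrom = sites$chrom[idx], pos = sites$pos[idx],
    ref = sites$ref[idx], alt = sites$alt[idx],
    gt = ifelse(g == 2L, "1/1", "0/1"),
    ref_depth = depth - ad_alt, alt_depth = ad_alt, depth = depth)
}

#' Simulate a cohort of individual-variant datasets
#'
#' Writes one VCF per individual, a panel BED, an individual-metadata
#' TSV and a dataset-metadata JSON under `dir`, all deterministic under
#' the recipe seed. Offspring receive one transmitted allele from the
#' parent per site (kinship expectation 0.25); duplicates share > 90% of
#' calls with their source but are byte-distinct; the noisy sample
#' carries calls at 95% of sites (above the cohort's Tukey upper fence
#' by construction) and the empty sample at 10 sites only.
#'
#' @param recipe a [cohort_recipe()].
#' @param dir output directory (created).
#' @return list with `dir`, `files` (named paths), `samples` (metadata
#'   table), `sites`, `reference` and `truth` (injected pathology ids:
#'   `noisy`, `empty`, `duplicates` -- data.table of pairs, `po_pairs`,
#'   `family_pairs`).
#' @export
simulate_cohort <- function(recipe, dir) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(recipe$seed)
  reference <- make_reference(recipe$seed + 1L, recipe$ref_length, chrom = "1")
  refseq <- reference[[1]]
  # biallelic SNV sites inside the panel; extra tail positions reserved
  # for noise / duplicate-perturbation calls
  all_pos <- sample.int(recipe$ref_length, recipe$n_sites * 2L)
  site_pos <- sort(all_pos[seq_len(recipe$n_sites)])
  extra_pos <- sort(all_pos[-seq_len(recipe$n_sites)])
  base_at <- function(p) substr(refseq, p, p)
  alt_of <- function(b) c(A = "G", C = "T", G = "A", T = "C", N = "A")[b]
  sites <- data.table::data.table(
    chrom = "1", pos = site_pos,
    ref = vapply(site_pos, base_at, ""),
    maf = rep_len(recipe$maf, recipe$n_sites))
  sites$alt <- unname(alt_of(sites$ref))
  extra_sites <- data.table::data.table(
    chrom = "1", pos = extra_pos,
    ref = vapply(extra_pos, base_at, ""))
  extra_sites$alt <- unname(alt_of(extra_sites$ref))

  samples <- list(); gts <- list()
  truth <- list(noisy = character(), empty = character(),
                duplicates = data.table::data.table(source = character(),
                                                    copy = character()),
                po_pairs = data.table::data.table(parent = character(),
                                                  offspring = character()),
                family_pairs = data.table::data.table(a = character(),
                                                      b = character()))
  sid <- 0L
  next_id <- function() { sid <<- sid + 1L; sprintf("S%03d", sid) }
  add_sample <- function(id, gt, family = NA_character_) {
    samples[[length(samples) + 1L]] <<- data.table::data.table(
      individual_id = id,
      sex = c("F", "M")[(length(samples) %% 2L) + 1L],
      suspicion = c("Hereditary breast and ovarian cancer syndrome",
                    "Lynch syndrome")[(length(samples) %% 2L) + 1L],
      family_id = family)
    gts[[id]] <<- gt
  }
  draw_gt <- function() stats::rbinom(recipe$n_sites, 2L, sites$maf)

  for (i in seq_len(recipe$n_unrelated)) add_sample(next_id(), draw_gt())
  for (i in seq_len(recipe$n_po_pairs)) {
    parent <- next_id(); offspring <- next_id()
    gp <- draw_gt()
    transmitted <- stats::rbinom(recipe$n_sites, 1L, gp / 2)
    other <- stats::rbinom(recipe$n_sites, 1L, sites$maf)
    add_sample(parent, gp)
    add_sample(offspring, transmitted + other)
    truth$po_pairs <- rbind(truth$po_pairs,
                            data.table::data.table(parent = parent,
                                                   offspring = offspring))
  }
  for (i in seq_len(recipe$n_family_pairs)) {
    a <- next_id(); b <- next_id()
    fam <- sprintf("FAM%02d", i)
    add_sample(a, draw_gt(), fam)
    add_sample(b, draw_gt(), fam)
    truth$family_pairs <- rbind(truth$family_pairs,
                                data.table::data.table(a = a, b = b))
  }
  dup_sources <- vapply(seq_len(recipe$n_duplicates), function(i)
    sprintf("S%03d", i), character(1))
  for (i in seq_len(recipe$n_duplicates)) {
    copy <- next_id()
    src <- dup_sources[i]
    gt <- gts[[src]]
    carried <- which(gt > 0L)
    drop <- sample(carried, max(1L, floor(length(carried) * 0.02)))
    gt[drop] <- 0L
    add_sample(copy, gt)
    truth$duplicates <- rbind(truth$duplicates,
                              data.table::data.table(source = src, copy = copy))
  }
  noisy_extra <- list()
  for (i in seq_len(recipe$n_noisy)) {
    id <- next_id()
    gt <- as.integer(stats::rbinom(recipe$n_sites, 1L, 0.95))
    add_sample(id, gt)
    noisy_extra[[id]] <- extra_sites[sample.int(nrow(extra_sites),
                                                floor(recipe$n_sites / 4))]
    truth$noisy <- c(truth$noisy, id)
  }
  for (i in seq_len(recipe$n_empty)) {
    id <- next_id()
    gt <- integer(recipe$n_sites)
    gt[sample.int(recipe$n_sites, 10L)] <- 1L
    add_sample(id, gt)
    truth$empty <- c(truth$empty, id)
  }
  samples <- data.table::rbindlist(samples)

  panel <- panel_regions("1", 1L, recipe$ref_length)
  files <- list()
  files$panel <- file.path(dir, "panel.bed")
  write_panel(panel, files$panel)
  files$reference <- file.path(dir, "reference.fa")
  write_reference(reference, files$reference)
  vcf_paths <- character(0)
  for (id in samples$individual_id) {
    calls <- .calls_from_gt(sites, gts[[id]], recipe$depth)
    if (!is.null(noisy_extra[[id]])) {
      ex <- noisy_extra[[id]]
      calls <- rbind(calls, data.table::data.table(
        chrom = ex$chrom, pos = ex$pos, ref = ex$ref, alt = ex$alt,
        gt = "0/1", ref_depth = recipe$depth %/% 2L,
        alt_depth = recipe$depth - recipe$depth %/% 2L,
        depth = recipe$depth))
    }
    p <- file.path(dir, paste0(id, ".vcf"))
    write_sample_vcf(calls, id, p, reference = reference)
    vcf_paths[id] <- p
  }
  files$vcfs <- vcf_paths
  files$individuals <- file.path(dir, "individuals.tsv")
  data.table::fwrite(samples, files$individuals, sep = "\t")
  files$metadata <- file.path(dir, "dataset.json")
  meta <- list(platform = "MiSeq", read_type = "paired-end",
               panel_version = "v1", panel_file = "panel.bed",
               genome_build = "GRCh37", aligner = "bwa-mem",
               caller = "GATK HaplotypeCaller", depth_threshold = 10L,
               dataset_id = sprintf("DS-%06d", recipe$seed))
  jsonlite::write_json(meta, files$metadata, auto_unbox = TRUE, pretty = TRUE)

  list(dir = dir, files = files, samples = samples, sites = sites,
       reference = reference, truth = truth)
}

#' Classification-fixture recipe reproducing the published cohort counts
#'
#' The default profile realizes the printed concordance and resolution
#' worked examples: 10 035 classified variants of which 2469 are
#' multi-classified (1697 full consensus, 367 five-tier-only discordant,
#' 321 three-tier-but-not-two discordant, 84 two-tier discordant), and a
#' per-case design for the 84 clinically significant discrepancies whose
#' scripted phase outcomes yield 93 + 52 revisions, 51/15/14 variants
#' resolved in Phases 1-3 and a 285-revision brute-force comparator.
#' The per-case composition is this package's own synthetic realization;
#' only the aggregate counts are published.
#'
#' @param n_single single-lab classified variants.
#' @param n_consensus multi-classified variants in full consensus.
#' @param n_five_only discordant under five-tier only.
#' @param n_three_not_two discordant under three-tier but two-tier
#'   concordant.
#' @param design data.table describing the two-tier discordant cases:
#'   columns `type`, `n_cases`, `n_labs`, `n_actionable` (group split),
#'   `rule` (expected Phase-1 rule) and `resolved_phase`
#'   (1, 2, 3 or NA).
#' @return list of class `classification_recipe`.
#' @export
classification_recipe <- function(n_single = 7566L, n_consensus = 1697L,
                                  n_five_only = 367L, n_three_not_two = 321L,
                                  design = NULL) {
  if (is.null(design)) design <- data.table::rbindlist(list(
    # resolved in Phase 1 (51 cases, 192 lab classifications)
    list(type = "A1", n_cases = 6L,  n_labs = 2L,  n_actionable = 1L, rule = "oldest",        resolved_phase = 1L),
    list(type = "A2", n_cases = 10L, n_labs = 3L,  n_actionable = 1L, rule = "outlier",       resolved_phase = 1L),
    list(type = "A3", n_cases = 25L, n_labs = 4L,  n_actionable = 1L, rule = "outlier",       resolved_phase = 1L),
    list(type = "A4", n_cases = 10L, n_labs = 5L,  n_actionable = 1L, rule = "outlier",       resolved_phase = 1L),
    # unresolved after Phase 1 (32 cases + the rule-"all" case)
    list(type = "B1a", n_cases = 10L, n_labs = 2L, n_actionable = 1L, rule = "oldest",        resolved_phase = 2L),
    list(type = "B1b", n_cases = 6L,  n_labs = 2L, n_actionable = 1L, rule = "oldest",        resolved_phase = 3L),
    list(type = "B1c", n_cases = 3L,  n_labs = 2L, n_actionable = 1L, rule = "oldest",        resolved_phase = NA_integer_),
    list(type = "B2a", n_cases = 4L,  n_labs = 3L, n_actionable = 1L, rule = "outlier",       resolved_phase = 2L),
    list(type = "B2b", n_cases = 6L,  n_labs = 3L, n_actionable = 1L, rule = "outlier",       resolved_phase = 3L),
    list(type = "B3a", n_cases = 1L,  n_labs = 5L, n_actionable = 1L, rule = "outlier",       resolved_phase = 2L),
    list(type = "B3b", n_cases = 1L,  n_labs = 5L, n_actionable = 1L, rule = "outlier",       resolved_phase = 3L),
    list(type = "B4",  n_cases = 1L,  n_labs = 5L, n_actionable = 2L, rule = "random-of-two", resolved_phase = NA_integer_),
    list(type = "C",   n_cases = 1L,  n_labs = 10L, n_actionable = 3L, rule = "all",          resolved_phase = 3L)))
  structure(list(n_single = n_single, n_consensus = n_consensus,
                 n_five_only = n_five_only, n_three_not_two = n_three_not_two,
                 design = design),
            class = "classification_recipe")
}

#' Generate per-lab classification tables and phase scripts
#'
#' Emits classification submissions realizing exactly the recipe's
#' concordance profile, with dates that drive the intended Phase-1 rule
#' for every two-tier discordant case, and the scripted post-review
#' labels per phase that realize the intended resolution outcomes (a
#' lab without a script entry reaffirms its label).
#'
#' @param recipe a [classification_recipe()].
#' @param labs lab id pool (at least `max(design$n_labs)`).
#' @return list with `classifications` (submission data.table: `key`,
#'   `lab`, `classification`, `date`, `row_in_file`), `scripts`
#'   (phase/key/lab/new_label), `design_cases` (per-case truth: `key`,
#'   `type`, `n_labs`, `rule`, `resolved_phase`) and `recipe`.
#' @export
make_classification_fixture <- function(recipe = classification_recipe(),
                                        labs = sprintf("L%02d", 1:10)) {
  design <- data.table::as.data.table(recipe$design)
  if (nrow(design) && max(design$n_labs) > length(labs))
    .stopf("lab pool too small: need %d labs", max(design$n_labs))
  five <- five_tier_labels()
  subs <- list(); scripts <- list(); cases <- list()
  vi <- 0L
  next_key <- function() {
    vi <<- vi + 1L
    sprintf("1:%d:A:G", 1000L + vi)
  }
  emit <- function(key, lab, label, date) {
    subs[[length(subs) + 1L]] <<- .dtab(
      key = key, lab = lab, classification = label, date = date)
  }
  script <- function(phase, key, lab, label) {
    scripts[[length(scripts) + 1L]] <<- .dtab(
      phase = phase, key = key, lab = lab, new_label = label)
  }
  base_date <- as.Date("2015-01-01")

  for (i in seq_len(recipe$n_single))
    emit(next_key(), labs[(i %% 2L) + 1L], five[(i %% 5L) + 1L],
         base_date + (i %% 1000L))
  for (i in seq_len(recipe$n_consensus)) {
    k <- next_key(); lab2 <- labs[c((i %% 3L) + 1L, (i %% 3L) + 2L)]
    label <- five[(i %% 5L) + 1L]
    emit(k, lab2[1], label, base_date + (i %% 900L))
    emit(k, lab2[2], label, base_date + (i %% 900L) + 30L)
  }
  for (i in seq_len(recipe$n_five_only)) {
    k <- next_key(); lab2 <- labs[c((i %% 3L) + 1L, (i %% 3L) + 2L)]
    pair <- if (i %% 2L) c("P", "LP") else c("LB", "B")
    emit(k, lab2[1], pair[1], base_date + (i %% 900L))
    emit(k, lab2[2], pair[2], base_date + (i %% 900L) + 30L)
  }
  for (i in seq_len(recipe$n_three_not_two)) {
    k <- next_key(); lab2 <- labs[c((i %% 3L) + 1L, (i %% 3L) + 2L)]
    pair <- if (i %% 2L) c("VUS", "LB") else c("VUS", "B")
    emit(k, lab2[1], pair[1], base_date + (i %% 900L))
    emit(k, lab2[2], pair[2], base_date + (i %% 900L) + 30L)
  }

  # two-tier discordant cases: actionable group first in lab order, so
  # the oldest classification (earliest date) sits in the actionable
  # group and the outlier (when n_actionable == 1) is the first lab
  ci <- 0L
  for (r in seq_len(nrow(design))) {
    row <- design[r]
    for (j in seq_len(row$n_cases)) {
      ci <- ci + 1L
      k <- next_key()
      case_labs <- labs[seq_len(row$n_labs)]
      act <- seq_len(row$n_actionable)
      labels <- ifelse(seq_len(row$n_labs) %in% act, "LP", "VUS")
      dates <- base_date + 2000L + ci * 3L + seq_len(row$n_labs) - 1L
      for (t in seq_len(row$n_labs))
        emit(k, case_labs[t], labels[t], dates[t])
      cases[[length(cases) + 1L]] <- .dtab(
        key = k, type = row$type, n_labs = row$n_labs, rule = row$rule,
        resolved_phase = row$resolved_phase)
      # scripted outcomes by design type
      rp <- row$resolved_phase
      if (row$rule %in% c("oldest", "outlier")) {
        assigned <- case_labs[1L]          # oldest date / lone actionable
        rest <- setdiff(case_labs, assigned)
        if (identical(rp, 1L)) {
          script(1L, k, assigned, "VUS")   # flip to majority group
        } else {
          # Phase 1 reaffirms; Phase 2 assigns the remaining labs
          if (identical(rp, 2L)) for (lb in rest) script(2L, k, lb, "LP")
          else if (identical(rp, 3L)) for (lb in case_labs) script(3L, k, lb, "VUS")
          # rp NA: everyone reaffirms throughout
        }
      } else if (row$rule == "random-of-two") {
        # no Phase 1/2 scripts: whichever lab the RNG assigns reaffirms;
        # unresolved through Phase 3 when rp is NA
        if (identical(rp, 3L)) for (lb in case_labs) script(3L, k, lb, "VUS")
      } else if (row$rule == "all") {
        # all review in Phase 1; all but one actionable lab concede
        for (lb in case_labs[act[-1L]]) script(1L, k, lb, "VUS")
        # dissenter (first lab) reaffirms in Phases 1-2, concedes in the
        # Phase-3 meeting
        if (identical(rp, 3L)) script(3L, k, case_labs[1L], "VUS")
      }
    }
  }
  classifications <- data.table::rbindlist(subs)
  classifications[, "row_in_file" := seq_len(nrow(classifications))]
  list(classifications = classifications,
       scripts = data.table::rbindlist(scripts),
       design_cases = data.table::rbindlist(cases),
       recipe = recipe)
}

#' Write per-lab classification fixture files
#'
#' Serializes a classification fixture to one TSV per lab (canonical
#' column layout) for exercising the ingestion layer.
#'
#' @param fixture output of [make_classification_fixture()].
#' @param dir output directory.
#' @return named character vector of file paths.
#' @export
write_classification_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- fixture$classifications
  parts <- data.table::tstrsplit(cl$key, ":", fixed = TRUE)
  tab <- data.table::data.table(
    chrom = parts[[1]], pos = parts[[2]], ref = parts[[3]], alt = parts[[4]],
    classification = cl$classification,
    date = format(cl$date, "%Y-%m-%d"), lab = cl$lab)
  paths <- character(0)
  for (lb in unique(tab$lab)) {
    p <- file.path(dir, paste0(lb, "_classifications.tsv"))
    data.table::fwrite(tab[tab$lab == lb,
                           c("chrom", "pos", "ref", "alt",
                             "classification", "date")], p, sep = "\t")
    paths[lb] <- p
  }
  paths
}
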