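# Synthetic-data generator: determinism and self-consistency.

test_that("make_reference is byte-reproducible and implants tracts", {
  p1 <- tempfile(fileext = ".fa"); p2 <- tempfile(fileext = ".fa")
  r1 <- make_reference(5, 500L, repeat_tracts = list(
    list(pos = 100L, unit = "AT", n = 4L)), path = p1)
  r2 <- make_reference(5, 500L, repeat_tracts = list(
    list(pos = 100L, unit = "AT", n = 4L)), path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(substr(r1[[1]], 100, 107), "ATATATAT")
  r3 <- make_reference(6, 500L)
  expect_false(identical(r1[[1]], r3[[1]]))
  back <- read_reference(p1)
  expect_identical(unname(back), unname(r1))
})

# one small cohort shared by the remaining tests (files in tempdir)
small_recipe <- cohort_recipe(seed = 303, n_unrelated = 6L, n_po_pairs = 1L,
                              n_family_pairs = 1L, n_duplicates = 1L,
                              n_noisy = 1L, n_empty = 1L, n_sites = 400L,
                              ref_length = 20000L)
cohort_dir <- file.path(tempdir(), "varconcord-test-cohort")
cohort <- simulate_cohort(small_recipe, cohort_dir)

load_profiles <- function(cx) {
  panel <- read_panel(cx$files$panel)
  profiles <- vector("list", length(cx$files$vcfs))
  for (i in seq_along(cx$files$vcfs)) {
    id <- names(cx$files$vcfs)[i]
    rec <- filter_records(read_sample_vcf(cx$files$vcfs[i], sample_id = id),
                          panel, 10)
    profiles[[i]] <- sample_profile(id, rec, panel, submission_order = i)
  }
  profiles
}

test_that("simulate_cohort writes parseable inputs for the whole pipeline", {
  expect_true(file.exists(cohort$files$panel))
  expect_true(all(file.exists(cohort$files$vcfs)))
  meta <- jsonlite::read_json(cohort$files$metadata, simplifyVector = TRUE)
  expect_silent(validate_metadata(as.list(meta)))
  ind <- data.table::fread(cohort$files$individuals)
  expect_equal(nrow(ind), nrow(cohort$samples))
  expect_true(all(c("individual_id", "sex", "suspicion") %in% names(ind)))
})

test_that("cohort files are byte-reproducible under the seed", {
  d2 <- file.path(tempdir(), "varconcord-test-cohort2")
  c2 <- simulate_cohort(small_recipe, d2)
  for (f in c("panel.bed", "individuals.tsv", names(cohort$files$vcfs)[1:3])) {
    f1 <- if (grepl("bed|tsv", f)) file.path(cohort_dir, f)
          else cohort$files$vcfs[f]
    f2 <- if (grepl("bed|tsv", f)) file.path(d2, f) else c2$files$vcfs[f]
    expect_identical(readLines(f1), readLines(f2), info = f)
  }
})

test_that("injected pathologies are detected by the sample tests", {
  profiles <- load_profiles(cohort)
  fam <- stats::setNames(cohort$samples$family_id,
                         cohort$samples$individual_id)
  qc <- sample_qc(profiles, fam)
  v <- qc$verdicts
  expect_equal(v$verdict[v$sample == cohort$truth$noisy], "noisy")
  expect_equal(v$verdict[v$sample == cohort$truth$empty], "empty")
  dup_pair <- cohort$truth$duplicates
  dup_score <- qc$pairs$duplicates
  sc <- dup_score$score[dup_score$sample1 == dup_pair$source &
                        dup_score$sample2 == dup_pair$copy]
  expect_gt(sc, 0.9)
  # later-submitted copy is the rejected one
  expect_equal(v$verdict[v$sample == dup_pair$copy], "duplicate")
  expect_equal(v$verdict[v$sample == dup_pair$source], "ok")
  # parent-offspring phi close to 0.25
  po <- cohort$truth$po_pairs
  kin <- qc$pairs$kinship
  phi <- kin$phi[kin$sample1 == po$parent & kin$sample2 == po$offspring]
  expect_lt(abs(phi - 0.25), 0.08)   # 400 sites: wide Monte-Carlo band
  # offspring shares >= 1 allele with the parent wherever the parent is hom-alt
  expect_true(all(v$insert[!v$sample %in% c(cohort$truth$noisy,
                                            cohort$truth$empty,
                                            dup_pair$copy)]))
  # family pair lands in one cluster
  fp <- cohort$truth$family_pairs
  expect_equal(qc$clusters[[fp$a]], qc$clusters[[fp$b]])
})

test_that("classification fixtures realize the requested profile exactly", {
  small <- classification_recipe(
    n_single = 10L, n_consensus = 20L, n_five_only = 5L,
    n_three_not_two = 4L,
    design = data.table::data.table(
      type = c("d2", "d3"), n_cases = c(3L, 2L), n_labs = c(2L, 3L),
      n_actionable = c(1L, 1L), rule = c("oldest", "outlier"),
      resolved_phase = c(1L, NA_integer_)))
  fx <- make_classification_fixture(small)
  led <- build_ledger(fx$classifications)
  s <- cohort_summary(led)
  expect_equal(s$n_classified, 10L + 20L + 5L + 4L + 5L)
  expect_equal(s$n_multi, 20L + 5L + 4L + 5L)
  expect_equal(s$n_consensus, 20L)
  expect_equal(s$n_discordant_three, 4L + 5L)
  expect_equal(s$n_discordant_two, 5L)
  # zero-discordance profile: planner has nothing to do
  none <- classification_recipe(n_single = 5L, n_consensus = 5L,
                                n_five_only = 0L, n_three_not_two = 0L,
                                design = data.table::data.table(
                                  type = character(), n_cases = integer(),
                                  n_labs = integer(), n_actionable = integer(),
                                  rule = character(),
                                  resolved_phase = integer()))
  fx0 <- make_classification_fixture(none)
  expect_length(discrepancy_cases(build_ledger(fx0$classifications)), 0L)
})

test_that("per-lab fixture files flow through the ingestion layer", {
  small <- classification_recipe(n_single = 4L, n_consensus = 6L,
                                 n_five_only = 2L, n_three_not_two = 2L,
                                 design = data.table::data.table(
                                   type = "d2", n_cases = 2L, n_labs = 2L,
                                   n_actionable = 1L, rule = "oldest",
                                   resolved_phase = 1L))
  fx <- make_classification_fixture(small)
  dir <- file.path(tempdir(), "varconcord-labs")
  paths <- write_classification_fixture(fx, dir)
  spec <- lab_format_spec(names(paths)[1],
    columns = c(chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
                classification = "classification", date = "date"))
  r <- parse_classifications(paths[1], spec)
  expect_true(r$accepted)
  orig <- fx$classifications[fx$classifications$lab == names(paths)[1]]
  expect_setequal(r$records$key, orig$key)
})
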