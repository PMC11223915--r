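# Three-phase discrepancy-resolution planner and revision accounting.

mk_case <- function(labs, labels, dates) {
  d <- data.table::data.table(lab = labs, classification = labels,
                              date = as.Date(dates))
  d$group <- tier_group(labels, "two")
  structure(list(key = "vX", labs = d), class = "discrepancy_case")
}

test_that("phase 1: two labs -> the oldest classification reviews", {
  case <- mk_case(c("L1", "L2"), c("P", "VUS"), c("2018-01-01", "2021-06-01"))
  a <- plan_phase1(case)
  expect_equal(a$labs, "L1")
  expect_equal(a$rule, "oldest")
})

test_that("phase 1: a lone lab opposing two or more is the outlier", {
  case <- mk_case(c("L1", "L2", "L3"), c("LP", "VUS", "B"),
                  c("2020-01-01", "2019-01-01", "2018-01-01"))
  a <- plan_phase1(case)
  expect_equal(a$labs, "L1")
  expect_equal(a$rule, "outlier")
})

test_that("phase 1: two-vs-many draws one lab from the two-lab group", {
  case <- mk_case(c("L1", "L2", "L3", "L4", "L5"),
                  c("LP", "P", "VUS", "B", "LB"),
                  sprintf("20%02d-01-01", 15:19))
  set.seed(1); a1 <- plan_phase1(case)
  expect_equal(a1$rule, "random-of-two")
  expect_true(a1$labs %in% c("L1", "L2"))
  expect_length(a1$labs, 1L)
  # determinism under a fixed seed
  set.seed(1); a2 <- plan_phase1(case)
  expect_identical(a1$labs, a2$labs)
})

test_that("phase 1 at 2v2: the group with the older classification is first", {
  case <- mk_case(c("L1", "L2", "L3", "L4"),
                  c("LP", "P", "VUS", "B"),
                  c("2020-01-01", "2021-01-01", "2016-01-01", "2022-01-01"))
  # non-actionable group holds the oldest (2016) classification
  set.seed(3)
  a <- plan_phase1(case)
  expect_equal(a$rule, "random-of-two")
  expect_true(a$labs %in% c("L3", "L4"))
})

test_that("phase 1: balanced many-lab cases assign everyone", {
  case <- mk_case(sprintf("L%d", 1:6),
                  c("LP", "P", "LP", "VUS", "B", "LB"),
                  sprintf("20%02d-01-01", 10:15))
  a <- plan_phase1(case)
  expect_equal(a$rule, "all")
  expect_length(a$labs, 6L)
  expect_error(plan_phase1(mk_case(c("L1", "L2"), c("P", "LP"),
                                   c("2020-01-01", "2021-01-01"))),
               "not two-tier discordant")
})

test_that("phase 2 assigns the remaining labs, or the single dissenter", {
  case <- mk_case(c("L1", "L2", "L3"), c("LP", "VUS", "B"),
                  sprintf("20%02d-01-01", 18:20))
  p1 <- plan_phase1(case)              # outlier L1
  p2 <- plan_phase2(case, p1)
  expect_equal(p2$labs, c("L2", "L3"))
  expect_equal(p2$rule, "remaining")

  # after an "all" phase 1 with a single dissenter
  post <- mk_case(c("L1", "L2", "L3", "L4"), c("LP", "VUS", "VUS", "VUS"),
                  sprintf("20%02d-01-01", 15:18))
  p2b <- plan_phase2(post, list(rule = "all", labs = post$labs$lab))
  expect_equal(p2b$labs, "L1")
  expect_equal(p2b$rule, "further-review")

  # more than one dissenter is flagged for manual handling
  post2 <- mk_case(c("L1", "L2", "L3", "L4", "L5"),
                   c("LP", "P", "VUS", "VUS", "VUS"),
                   sprintf("20%02d-01-01", 15:19))
  expect_warning(p2c <- plan_phase2(post2, list(rule = "all",
                                                labs = post2$labs$lab)),
                 "manual")
  expect_equal(p2c$rule, "manual")
  expect_length(p2c$labs, 0L)
})

test_that("phase 3: email group up to three labs, meeting for four or more", {
  two <- mk_case(c("L1", "L2"), c("P", "VUS"), c("2018-01-01", "2019-01-01"))
  three <- mk_case(c("L1", "L2", "L3"), c("P", "VUS", "VUS"),
                   sprintf("20%02d-01-01", 17:19))
  four <- mk_case(sprintf("L%d", 1:4), c("P", "VUS", "VUS", "VUS"),
                  sprintf("20%02d-01-01", 16:19))
  expect_equal(plan_phase3(two)$rule, "email-group")
  expect_equal(plan_phase3(three)$rule, "email-group")
  expect_equal(plan_phase3(four)$rule, "meeting")
  expect_length(plan_phase3(four)$labs, 4L)
})

test_that("execute_resolution + account reproduce a small scripted fixture", {
  subs <- rbind(
    data.frame(key = "v1", lab = c("L1", "L2"), classification = c("LP", "VUS"),
               date = as.Date(c("2018-01-01", "2020-01-01"))),
    data.frame(key = "v2", lab = c("L1", "L2", "L3"),
               classification = c("LP", "VUS", "VUS"),
               date = as.Date(c("2019-01-01", "2020-01-01", "2021-01-01"))))
  led <- build_ledger(subs)
  scripts <- data.frame(phase = c(1L, 2L), key = c("v1", "v2"),
                        lab = c("L1", "L2"), new_label = c("VUS", "LP"))
  # v1: oldest L1 concedes in phase 1; v2: outlier L1 reaffirms, phase 2
  # has L2 flip but L3 still disagrees -> phase 3 email group, no script
  res <- execute_resolution(led, scripts, seed = 5)
  acc <- account(res$log, res$cases)
  expect_equal(res$cases$resolved_phase[res$cases$key == "v1"], 1L)
  expect_true(is.na(res$cases$resolved_phase[res$cases$key == "v2"]))
  expect_equal(acc$phases$revisions, c(2L, 2L, 0L))  # L1+L1, then L2+L3
  expect_equal(acc$phases$resolved, c(1L, 0L, 0L))
  expect_equal(acc$total_revisions, 4L)
  expect_equal(acc$brute_force_revisions, 5L)
  expect_equal(acc$phases$pct_resolved, c(50.0, 0.0, 0.0))
})

test_that("economy: planner revisions never exceed brute force", {
  set.seed(12)
  five <- five_tier_labels()
  for (rep in 1:40) {
    n_cases <- sample(1:6, 1)
    subs <- do.call(rbind, lapply(seq_len(n_cases), function(ci) {
      repeat {
        n <- sample(2:6, 1)
        labels <- sample(five, n, replace = TRUE)
        if (length(unique(tier_group(labels, "two"))) == 2L) break
      }
      data.frame(key = sprintf("c%d", ci), lab = sprintf("L%d", seq_len(n)),
                 classification = labels,
                 date = as.Date("2018-01-01") + sample(0:1000, n))
    }))
    led <- build_ledger(subs)
    res <- suppressWarnings(execute_resolution(led, scripts = NULL, seed = rep))
    acc <- account(res$log, res$cases)
    expect_lte(acc$total_revisions, acc$brute_force_revisions)
    # every initially discordant case received a phase-1 assignment
    p1 <- res$phase_rules[res$phase_rules$phase == 1L]
    expect_setequal(p1$key, res$cases$key)
    expect_true(all(p1$n_assigned >= 1L))
  }
})

test_that("labs review at most once across phases 1-2 per case", {
  set.seed(77)
  five <- five_tier_labels()
  for (rep in 1:20) {
    repeat {
      n <- sample(2:7, 1)
      labels <- sample(five, n, replace = TRUE)
      if (length(unique(tier_group(labels, "two"))) == 2L) break
    }
    subs <- data.frame(key = "v", lab = sprintf("L%d", seq_len(n)),
                       classification = labels,
                       date = as.Date("2018-01-01") + sample(0:999, n))
    led <- build_ledger(subs)
    res <- suppressWarnings(execute_resolution(led, NULL, seed = rep))
    l12 <- res$log[res$log$phase <= 2L]
    expect_lte(nrow(l12), n)
    expect_false(anyDuplicated(l12$lab) > 0)
  }
})
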