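test_that("race-assumption check compares the category means strictly", {
  tr <- make_trials(go_rt = c(1.0, 1.1), sr_rt = c(0.8, 0.9),
                    sr_ssd = c(0.25, 0.30))
  res <- check_race_assumption(tr)
  expect_true(res$race_assumption_ok)
  expect_equal(res$mean_signal_respond_rt, 0.85)
  expect_equal(res$mean_go_rt, 1.05)

  # identical means fail the strict inequality
  tr_eq <- make_trials(go_rt = c(0.8, 0.9), sr_rt = c(0.8, 0.9),
                       sr_ssd = c(0.25, 0.30))
  expect_false(check_race_assumption(tr_eq)$race_assumption_ok)

  expect_error(check_race_assumption(make_trials(go_rt = c(1, 1.1))),
               "signal-respond")
})

test_that("race-model data satisfy the race assumption almost surely", {
  des <- task_design(n_trials = 450, n_blocks = 9)
  ok <- vapply(1:40, function(i) {
    sim <- simulate_session(des, ref_race(p_tf = 0.06, p_gf = 0.02),
                            seed = 100 + i)
    check_race_assumption(sim)$race_assumption_ok
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("responding-rate bounds implement the 0.25-0.75 screen", {
  tr <- make_trials(go_rt = 1, sr_rt = rep(0.8, 40),
                    sr_ssd = rep(0.3, 40), inhib_ssd = rep(0.3, 72))
  res <- check_p_respond_bounds(tr)
  expect_equal(res$p_respond_signal, 40 / 112, tolerance = 1e-12)
  expect_true(res$p_respond_in_bounds)

  tr_low <- make_trials(go_rt = 1, sr_rt = rep(0.8, 20),
                        sr_ssd = rep(0.3, 20), inhib_ssd = rep(0.3, 92))
  expect_false(check_p_respond_bounds(tr_low)$p_respond_in_bounds)
})

test_that("Tukey fences use type-7 quartiles", {
  f <- tukey_fences(c(1, 2, 3, 4, 100))
  # Q1 = 2, Q3 = 4, IQR = 2 by linear interpolation of order statistics
  expect_equal(unname(f), c(2 - 3, 4 + 3))
  expect_true(100 > f[["upper"]])

  f0 <- tukey_fences(rep(0.99, 6))
  expect_equal(unname(f0), c(0.99, 0.99))

  fs <- tukey_fences(1:11)
  expect_equal(mean(fs), 6)  # symmetric about the median

  expect_error(tukey_fences(c(1, 2, 3)), "at least 4")
})

test_that("anticipatory responses are removed idempotently", {
  tr <- make_trials(go_rt = c(0.15, 0.25, 0.30))
  res <- remove_anticipatory(tr)
  expect_equal(res$n_removed, 1L)
  expect_true(all(res$trials$rt >= 0.2, na.rm = TRUE))
  res2 <- remove_anticipatory(res$trials)
  expect_equal(res2$n_removed, 0L)
  expect_identical(res2$trials, res$trials)

  # enumerated toy table: two sub-threshold rows of five survive removal
  toy <- make_trials(go_rt = c(0.10, 0.19, 0.25, 0.80, 1.20))
  expect_equal(remove_anticipatory(toy)$n_removed, 2L)
  expect_equal(nrow(remove_anticipatory(toy)$trials), 3L)
})

test_that("cohort screen aggregates checks and session completeness", {
  # full-length sessions: the responding-rate screen needs the staircase
  # to have settled
  des <- task_design(n_trials = 450, n_blocks = 9)
  cohort <- simulate_cohort(6, population_defaults(), des, seed = 30,
                            conditions = c("a", "b", "c"))
  tr <- cohort$trials
  # a clean simulated cohort passes wholesale
  qc_all <- suppressWarnings(qc_cohort(tr, required_sessions = 3))
  expect_true(all(qc_all$include))

  # dropping one subject's third session excludes that subject only
  tr_inc <- tr[!(tr$subject == "s02" & tr$condition == "c"), ]
  qc_inc <- suppressWarnings(qc_cohort(tr_inc, required_sessions = 3))
  expect_true(all(!qc_inc$include[qc_inc$subject == "s02"]))
  expect_true(all(qc_inc$include[qc_inc$subject != "s02"]))

  # an injected low-accuracy subject is the only Tukey outlier
  tr_bad <- tr
  bad <- tr_bad$subject == "s03" & tr_bad$trial_type == "go" & tr_bad$response
  set.seed(1)
  tr_bad$choice_correct[bad] <- runif(sum(bad)) < 0.6
  qc_bad <- suppressWarnings(qc_cohort(tr_bad, required_sessions = 3))
  flagged <- unique(qc_bad$subject[qc_bad$go_accuracy_outlier])
  expect_identical(flagged, "s03")
  expect_true(all(!qc_bad$include[qc_bad$subject == "s03"]))
})

test_that("qc decisions are invariant to row order", {
  des <- task_design(n_trials = 90, n_blocks = 9)
  cohort <- simulate_cohort(4, population_defaults(), des, seed = 33,
                            conditions = c("a", "b"))
  tr <- cohort$trials
  qc1 <- suppressWarnings(qc_cohort(tr, required_sessions = 2))
  shuffled <- withr::with_seed(1, tr[sample(nrow(tr)), ])
  qc2 <- suppressWarnings(qc_cohort(shuffled, required_sessions = 2))
  key <- c("subject", "condition")
  qc2 <- qc2[match(paste(qc1$subject, qc1$condition),
                   paste(qc2$subject, qc2$condition)), ]
  expect_equal(qc1$include, qc2$include)
  expect_equal(qc1$p_respond_signal, qc2$p_respond_signal)
  expect_equal(qc1$mean_go_rt, qc2$mean_go_rt)
})

test_that("near-uniform go RTs raise the strategic-responding advisory", {
  # a subject whose go RTs are uniform on [0.4, 1.6]
  n <- 120
  uni <- make_trials(go_rt = seq(0.4, 1.6, length.out = n),
                     sr_rt = rep(0.7, 20), sr_ssd = rep(0.3, 20),
                     inhib_ssd = rep(0.3, 20))
  des <- task_design(n_trials = 90, n_blocks = 9)
  normal <- purrr::map_dfr(1:5, function(i) {
    s <- simulate_session(des, ref_race(), seed = 40 + i,
                          subject = sprintf("n%02d", i))
    s$condition <- "c1"
    s
  })
  both <- dplyr::bind_rows(uni, normal)
  expect_warning(qc <- qc_cohort(both, required_sessions = 1),
                 "strategic")
  row <- qc[qc$subject == "s01", ][1, ]
  expect_true(row$strategic_flag)
  # advisory only: inclusion is exactly the conjunction of the hard checks
  expect_equal(row$include,
               row$race_assumption_ok && row$p_respond_in_bounds &&
                 !row$go_accuracy_outlier && row$complete_sessions == 1)
  expect_false(any(qc$strategic_flag[qc$subject != "s01"]))
})
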