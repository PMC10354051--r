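test_that("task_design validates its invariants", {
  expect_error(task_design(n_trials = 451, n_blocks = 9), "divisible")
  expect_error(task_design(p_stop = 0), "p_stop")
  expect_error(task_design(ssd_step = 0), "staircase")
  d <- task_design()
  expect_equal(d$n_trials, 450L)
  expect_equal(d$ssd_initial, 0.25)
})

test_that("a session has the designed shape and deterministic stop count", {
  des <- task_design()
  sim <- simulate_session(des, ref_race(), seed = 1)
  expect_equal(nrow(sim), 450L)
  expect_equal(sum(sim$trial_type == "stop"), 112L)  # round(450 * 0.25)
  expect_equal(length(unique(sim$block)), 9L)
  # per-block stop counts are fixed by the permutation schedule
  counts <- table(sim$block[sim$trial_type == "stop"])
  expect_true(all(counts %in% c(12L, 13L)))
  # schema invariants
  expect_true(all(is.na(sim$ssd[sim$trial_type == "go"])))
  expect_true(all(!is.na(sim$ssd[sim$trial_type == "stop"])))
  expect_true(all(is.na(sim$rt) == !sim$response))
})

test_that("the same seed reproduces a session exactly", {
  des <- task_design(n_trials = 90, n_blocks = 9)
  a <- simulate_session(des, ref_race(p_tf = 0.05, p_gf = 0.02), seed = 5)
  b <- simulate_session(des, ref_race(p_tf = 0.05, p_gf = 0.02), seed = 5)
  expect_identical(a, b)
  c <- simulate_session(des, ref_race(p_tf = 0.05, p_gf = 0.02), seed = 6)
  expect_false(identical(a, c))
})

test_that("the staircase starts at ssd_initial, steps by ssd_step and
          respects its bounds", {
  des <- task_design()
  sim <- simulate_session(des, ref_race(), seed = 3)
  st <- sim[sim$trial_type == "stop", ]
  expect_equal(st$ssd[1], des$ssd_initial)
  expect_true(all(st$ssd >= des$ssd_min & st$ssd <= des$ssd_max))
  # successive delays move one step against the previous outcome
  step <- diff(st$ssd)
  expected <- ifelse(st$response[-nrow(st)], -des$ssd_step, des$ssd_step)
  at_bound <- st$ssd[-nrow(st)] %in% c(des$ssd_min, des$ssd_max)
  expect_true(all(abs(step - expected) < 1e-12 | at_bound))
})

test_that("the staircase tracks 50% responding without failures", {
  des <- task_design(n_trials = 40000, n_blocks = 10)
  sim <- simulate_session(des, ref_race(), seed = 8)
  st <- sim[sim$trial_type == "stop", ]
  expect_gte(nrow(st), 10000)
  expect_gte(mean(st$response), 0.47)
  expect_lte(mean(st$response), 0.53)
})

test_that("simulated go RTs and failure rates match the generator", {
  r <- ref_race(p_gf = 0.1)
  des <- task_design(n_trials = 20000, n_blocks = 10)
  sim <- simulate_session(des, r, seed = 9)
  go <- sim[sim$trial_type == "go", ]
  # mean correct go RT -> mu + tau
  se <- sqrt(0.09^2 + 0.10^2) / sqrt(sum(go$response))
  expect_lt(abs(mean(go$rt[go$response]) - 0.97), 4 * se)
  # omission rate -> p_gf (deadline censoring adds a negligible sliver)
  p_omit <- mean(!go$response)
  expect_lt(abs(p_omit - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(go)) + 1e-3)
})

test_that("cohort simulation returns the full crossing and its truth table", {
  des <- task_design(n_trials = 45, n_blocks = 9)
  cohort <- simulate_cohort(23, population_defaults(), des, seed = 4,
                            conditions = c("rDLPFC", "rIFG", "sham"))
  expect_equal(nrow(cohort$trials), 23 * 3 * 45)
  expect_equal(nrow(cohort$params), 23 * 3)
  expect_setequal(unique(cohort$trials$condition),
                  c("rDLPFC", "rIFG", "sham"))
  # probability-scale truths match the probit draws
  expect_equal(cohort$params$p_tf, pnorm(cohort$params$z_tf))
})

test_that("a degenerate population (zero scales) collapses to the location", {
  loc <- population_defaults()$location
  pop0 <- population_params(loc, setNames(rep(0, 8), names(loc)))
  des <- task_design(n_trials = 45, n_blocks = 9)
  cohort <- simulate_cohort(3, pop0, des, seed = 2)
  expect_true(all(abs(cohort$params$mu_go - loc[["mu_go"]]) < 1e-12))
  expect_true(all(abs(cohort$params$z_tf - loc[["z_tf"]]) < 1e-12))
  # negative scales are rejected
  expect_error(population_params(loc, setNames(rep(-1, 8), names(loc))),
               "scale")
})

test_that("across-subject spread of drawn parameters matches the
          population scale", {
  des <- task_design(n_trials = 36, n_blocks = 9)
  cohort <- simulate_cohort(200, population_defaults(), des, seed = 12)
  sd_mu_go <- sd(cohort$params$mu_go)
  # SE of an SD estimate ~ scale / sqrt(2 (n - 1))
  se <- 0.12 / sqrt(2 * 199)
  expect_lt(abs(sd_mu_go - 0.12), 3 * se)
})

test_that("per-subject streams make cohort subsets reproducible", {
  des <- task_design(n_trials = 45, n_blocks = 9)
  big <- simulate_cohort(5, population_defaults(), des, seed = 7)
  small <- simulate_cohort(3, population_defaults(), des, seed = 7)
  expect_identical(
    big$trials[big$trials$subject %in% c("s01", "s02", "s03"), ],
    small$trials)
})
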