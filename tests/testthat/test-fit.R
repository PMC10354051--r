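test_that("prior_spec enforces sane bounds", {
  p <- prior_spec()
  expect_equal(unname(p$lower[["mu_go"]]), 0.001)
  expect_equal(unname(p$upper[["mu_go"]]), 3)
  expect_equal(unname(p$upper[["mu_stop"]]), 2)
  expect_equal(p$scale_upper, 1)
  expect_error(prior_spec(lower = c(mu_go = 5)), "lower < upper")
})

test_that("log_posterior floors out-of-bound parameters", {
  des <- task_design(n_trials = 45, n_blocks = 9)
  cohort <- simulate_cohort(2, population_defaults(), des, seed = 80)
  tr <- cohort$trials
  pm <- as.matrix(cohort$params[, race_param_names()])
  pop <- list(location = population_defaults()$location,
              scale = population_defaults()$scale)
  base <- log_posterior(tr, pm, pop)
  expect_true(is.finite(base) && base > -1e9)

  pm_bad <- pm
  pm_bad[1, "sigma_go"] <- -0.1
  expect_equal(log_posterior(tr, pm_bad, pop), -1e10)
  pop_bad <- pop
  pop_bad$scale[["mu_go"]] <- 5
  expect_equal(log_posterior(tr, pm, pop_bad), -1e10)
})

test_that("log_posterior recomputes as likelihood plus group densities", {
  des <- task_design(n_trials = 45, n_blocks = 9)
  cohort <- simulate_cohort(3, population_defaults(), des, seed = 81)
  tr <- cohort$trials
  pm <- as.matrix(cohort$params[, race_param_names()])
  pop <- list(location = population_defaults()$location,
              scale = population_defaults()$scale)
  # independent reassembly through the R reference path
  b <- stopsignal:::race_param_bounds()
  expected <- 0
  subs <- sort(unique(tr$subject))
  for (j in seq_along(subs)) {
    d <- tr[tr$subject == subs[j], ]
    r <- race_params(go = pm[j, 1:3], stop = pm[j, 4:6],
                     p_tf = pnorm(pm[j, 7]), p_gf = pnorm(pm[j, 8]))
    expected <- expected + table_loglik(d, r)
    z <- pnorm(b$upper, pop$location, pop$scale) -
      pnorm(b$lower, pop$location, pop$scale)
    expected <- expected +
      sum(dnorm(pm[j, ], pop$location, pop$scale, log = TRUE) - log(z))
  }
  expect_equal(log_posterior(tr, pm, pop), expected, tolerance = 1e-6)
})

test_that("with a vague hierarchy the posterior moves like the likelihood", {
  des <- task_design(n_trials = 90, n_blocks = 9)
  cohort <- simulate_cohort(1, population_defaults(), des, seed = 82)
  tr <- cohort$trials
  pm1 <- as.matrix(cohort$params[, race_param_names()])
  pm2 <- pm1
  pm2[1, "mu_go"] <- pm1[1, "mu_go"] + 0.002
  pop <- list(location = population_defaults()$location,
              scale = setNames(rep(0.9, 8), race_param_names()))
  d_post <- log_posterior(tr, pm2, pop) - log_posterior(tr, pm1, pop)
  r1 <- race_params(go = pm1[1, 1:3], stop = pm1[1, 4:6],
                    p_tf = pnorm(pm1[1, 7]), p_gf = pnorm(pm1[1, 8]))
  r2 <- race_params(go = pm2[1, 1:3], stop = pm2[1, 4:6],
                    p_tf = pnorm(pm2[1, 7]), p_gf = pnorm(pm2[1, 8]))
  d_lik <- table_loglik(tr, r2) - table_loglik(tr, r1)
  expect_lt(abs(d_post - d_lik), 0.01)
})

test_that("fits are reproducible and refuse mixed conditions", {
  des <- task_design(n_trials = 60, n_blocks = 6)
  cohort <- simulate_cohort(2, population_defaults(), des, seed = 83)
  f1 <- fit_beests(cohort$trials, chains = 2, iter = 300, burn = 150,
                   seed = 9)
  f2 <- fit_beests(cohort$trials, chains = 2, iter = 300, burn = 150,
                   seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_beests(cohort$trials, chains = 2, iter = 300, burn = 150,
                   seed = 10)
  expect_false(identical(f1$draws, f3$draws))

  two_cond <- simulate_cohort(2, population_defaults(), des, seed = 84,
                              conditions = c("a", "b"))
  expect_error(fit_beests(two_cond$trials), "one condition")
})

test_that("the likelihood is invariant to trial order", {
  des <- task_design(n_trials = 90, n_blocks = 9)
  sim <- simulate_session(des, ref_race(p_tf = 0.06, p_gf = 0.02),
                          seed = 85)
  r <- ref_race(p_tf = 0.06, p_gf = 0.02)
  shuffled <- withr::with_seed(3, sim[sample(nrow(sim)), ])
  expect_equal(table_loglik(sim, r), table_loglik(shuffled, r),
               tolerance = 1e-9)
})

test_that("with no trials the sampler reproduces the hyperpriors", {
  # Geweke-style check: an empty likelihood leaves the uniform
  # hyper-location posteriors; their draws should match the prior mean
  # within Monte-Carlo error for a bounded parameter
  dat <- list(s01 = list(go_rt = numeric(), n_go_omit = 0L,
                         sr_rt = numeric(), sr_ssd = numeric(),
                         inhib_ssd = numeric(), inhib_n = integer()),
              s02 = list(go_rt = numeric(), n_go_omit = 0L,
                         sr_rt = numeric(), sr_ssd = numeric(),
                         inhib_ssd = numeric(), inhib_n = integer()))
  priors <- prior_spec()
  init <- rbind(s01 = stopsignal:::init_subject(dat$s01, priors),
                s02 = stopsignal:::init_subject(dat$s02, priors))
  # drive run_chain directly with empty data
  res <- withr::with_seed(1, stopsignal:::run_chain(
    dat, priors, init, iter = 24000, burn = 4000, thin = 1, n_keep = 20000,
    seed = 123, jitter = 0, single_subject = FALSE))
  # mu_stop hyper-location is Uniform(0.001, 2): mean 1.0005, sd 0.577;
  # the tolerance reflects the chain's autocorrelation, not the draw count
  mu_stop_loc <- res$draws[, 4]
  expect_lt(abs(mean(mu_stop_loc) - 1.0005), 0.12)
  expect_lt(abs(sd(mu_stop_loc) - (2 - 0.001) / sqrt(12)), 0.1)
})
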