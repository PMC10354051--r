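test_that("race_params validates failure probabilities", {
  expect_error(race_params(go = c(0.9, 0.1, 0.1), stop = c(0.4, 0.05, 0.05),
                           p_tf = 1.2), "p_tf")
  expect_error(race_params(go = c(0.9, 0.1, 0.1), stop = c(0.4, 0.05, 0.05),
                           p_gf = -0.1), "p_gf")
})

test_that("p_respond_given_ssd has the limiting behaviours of the race", {
  r <- race_params(go = c(0.87, 0.10, 0.10), stop = c(0.41, 0.04, 0.05),
                   p_gf = 0.02)
  # stop runner can never win at a huge delay
  expect_equal(p_respond_given_ssd(r, 1e6), 1 - 0.02, tolerance = 1e-8)
  # stop never triggers
  r_tf <- race_params(go = c(0.87, 0.10, 0.10), stop = c(0.41, 0.04, 0.05),
                      p_tf = 1, p_gf = 0.02)
  expect_equal(p_respond_given_ssd(r_tf, 0.3), 1 - 0.02, tolerance = 1e-12)
  # exchangeable runners at zero delay
  r_sym <- race_params(go = c(0.6, 0.08, 0.07), stop = c(0.6, 0.08, 0.07))
  expect_equal(p_respond_given_ssd(r_sym, 0), 0.5, tolerance = 1e-6)
  # monotone nondecreasing in ssd, bounded by 1 - p_gf
  ps <- p_respond_given_ssd(r, seq(0, 1.2, by = 0.05))
  expect_true(all(diff(ps) >= -1e-12))
  expect_true(all(ps <= 1 - 0.02 + 1e-12))
})

test_that("responding probability is monotone in the runner means", {
  mu_stops <- seq(0.3, 0.6, by = 0.05)
  p1 <- vapply(mu_stops, function(m) {
    p_respond_given_ssd(race_params(go = c(0.9, 0.1, 0.1),
                                    stop = c(m, 0.04, 0.05)), 0.3)
  }, numeric(1))
  expect_true(all(diff(p1) > 0))  # slower stop runner -> more responses
  mu_gos <- seq(0.7, 1.1, by = 0.05)
  p2 <- vapply(mu_gos, function(m) {
    p_respond_given_ssd(race_params(go = c(m, 0.1, 0.1),
                                    stop = c(0.42, 0.04, 0.05)), 0.3)
  }, numeric(1))
  expect_true(all(diff(p2) < 0))  # slower go runner -> fewer responses
})

test_that("race probability matches a Monte-Carlo race oracle", {
  r <- race_params(go = c(0.87, 0.10, 0.10), stop = c(0.41, 0.04, 0.05))
  ssd <- 0.48
  p_hat <- withr::with_seed(21, {
    t_go <- rexgauss(1e6, r$go)
    t_stop <- rexgauss(1e6, r$stop)
    mean(t_go < ssd + t_stop)
  })
  se <- sqrt(p_hat * (1 - p_hat) / 1e6)
  expect_lt(abs(p_respond_given_ssd(r, ssd) - p_hat), 3 * se)
})

test_that("signal-respond density reduces to the go density and integrates
          to the responding probability", {
  r <- ref_race()
  t <- c(0.7, 0.9, 1.2)
  expect_equal(signal_respond_logdensity(t, r, ssd = 1e6),
               dexgauss(t, r$go, log = TRUE), tolerance = 1e-9)
  for (ssd in c(0.2, 0.48)) {
    int <- stats::integrate(
      function(t) exp(signal_respond_logdensity(t, r, ssd, floor = -Inf)),
      -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(int, p_respond_given_ssd(r, ssd), tolerance = 1e-6)
  }
})

test_that("signal-respond density matches Monte-Carlo signal-respond RTs", {
  r <- race_params(go = c(0.87, 0.10, 0.10), stop = c(0.41, 0.04, 0.05))
  ssd <- 0.48
  # binned-probability oracle around t = 0.9: model mass in [0.85, 0.95]
  # vs the simulated share of races the go runner wins in that window
  model_mass <- stats::integrate(
    function(t) exp(signal_respond_logdensity(t, r, ssd, floor = -Inf)),
    0.85, 0.95, rel.tol = 1e-9)$value
  mc_mass <- withr::with_seed(22, {
    t_go <- rexgauss(1e6, r$go)
    t_stop <- rexgauss(1e6, r$stop)
    mean(t_go < ssd + t_stop & t_go >= 0.85 & t_go <= 0.95)
  })
  se <- sqrt(mc_mass * (1 - mc_mass) / 1e6)
  expect_lt(abs(model_mass - mc_mass), 3 * se)
})

test_that("trial log-likelihood covers the four outcomes and flags bad rows", {
  r <- ref_race(p_gf = 0.018)
  omission <- list(trial_type = "go", response = FALSE, rt = NA, ssd = NA)
  expect_equal(trial_loglik(omission, r), log(0.018))
  go_resp <- list(trial_type = "go", response = TRUE, rt = 0.95, ssd = NA)
  expect_equal(trial_loglik(go_resp, r),
               log(1 - 0.018) + dexgauss(0.95, r$go, log = TRUE))
  # impossible outcome: inhibition with certain trigger failure -> floor
  r_imp <- ref_race(p_tf = 1)
  inhib <- list(trial_type = "stop", response = FALSE, rt = NA, ssd = 0.3)
  expect_equal(trial_loglik(inhib, r_imp), -700)
  # inconsistent records
  expect_error(trial_loglik(list(trial_type = "go", response = TRUE,
                                 rt = NA, ssd = NA), r), "rt")
  expect_error(trial_loglik(list(trial_type = "go", response = TRUE,
                                 rt = 0.5, ssd = 0.2), r), "ssd")
  expect_error(trial_loglik(list(trial_type = "stop", response = FALSE,
                                 rt = NA, ssd = NA), r), "ssd")
})

test_that("stop-trial outcome probabilities sum to one", {
  for (r in list(ref_race(), ref_race(p_tf = 0.1, p_gf = 0.05))) {
    for (ssd in c(0.15, 0.45)) {
      respond_mass <- stats::integrate(
        function(t) exp(signal_respond_logdensity(t, r, ssd, floor = -Inf)),
        -Inf, Inf, rel.tol = 1e-9)$value
      inhibit_mass <- 1 - p_respond_given_ssd(r, ssd)
      # the go-failure branch of an executed-response trial is the missing
      # go-runner mass
      gf_mass <- r$p_gf
      expect_equal(respond_mass + inhibit_mass, 1, tolerance = 1e-6)
      expect_true(inhibit_mass >= gf_mass - 1e-9)
    }
  }
})

test_that("compiled table likelihood equals the summed R reference path", {
  r <- ref_race(p_tf = 0.06, p_gf = 0.02)
  sim <- simulate_session(task_design(n_trials = 90, n_blocks = 9), r,
                          seed = 31)
  ll_r <- sum(vapply(seq_len(nrow(sim)),
                     function(i) trial_loglik(sim[i, ], r), numeric(1)))
  expect_equal(table_loglik(sim, r), ll_r, tolerance = 1e-7)
})

test_that("race probabilities are unit-invariant (ms vs s)", {
  r_s <- race_params(go = c(0.87, 0.10, 0.10), stop = c(0.41, 0.04, 0.05),
                     p_tf = 0.05, p_gf = 0.02)
  r_ms <- race_params(go = c(870, 100, 100), stop = c(410, 40, 50),
                      p_tf = 0.05, p_gf = 0.02)
  for (ssd in c(0.2, 0.48)) {
    expect_equal(p_respond_given_ssd(r_ms, ssd * 1000),
                 p_respond_given_ssd(r_s, ssd), tolerance = 1e-7)
  }
})
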