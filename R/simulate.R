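#' Stop-signal task design
#'
#' Describes one session of the staircase-tracked stop-signal task. The
#' defaults reproduce the gamified task design this package emulates:
#' 450 trials in 9 blocks, a 2000 ms response deadline, stop signals on a
#' quarter of trials with the stop-signal delay (SSD) starting at 250 ms
#' and tracked by a 1-up/1-down staircase in 50 ms steps (targeting 50%
#' responding on stop trials), and an inter-trial interval drawn uniformly
#' between 500 and 1500 ms.
#'
#' @param n_trials Trials per session; must be divisible by `n_blocks`.
#' @param n_blocks Number of blocks.
#' @param p_stop Proportion of stop trials (scheduled by within-block
#'   permutation with a fixed per-block count, so the realised count is
#'   deterministic).
#' @param ssd_initial,ssd_step,ssd_min,ssd_max Staircase start, step and
#'   clamp bounds, seconds.
#' @param response_deadline Go-stimulus deadline, seconds; slower responses
#'   are recorded as omissions.
#' @param iti_range Inter-trial interval range, seconds (logged only; no
#'   model consequence).
#' @param p_choice_error Probability a responded go trial is a wrong-side
#'   choice error.
#'
#' @return An object of class `task_design`.
#' @export
task_design <- function(n_trials = 450L, n_blocks = 9L, p_stop = 0.25,
                        ssd_initial = 0.25, ssd_step = 0.05,
                        ssd_min = 0.05, ssd_max = 2.0,
                        response_deadline = 2.0,
                        iti_range = c(0.5, 1.5),
                        p_choice_error = 0.01) {
  stopifnot(n_trials >= 1, n_blocks >= 1)
  if (n_trials %% n_blocks != 0) {
    rlang::abort("`n_trials` must be divisible by `n_blocks`")
  }
  if (p_stop <= 0 || p_stop >= 1) rlang::abort("`p_stop` must be in (0, 1)")
  if (ssd_min < 0 || ssd_step <= 0 || ssd_max <= ssd_min) {
    rlang::abort("invalid staircase bounds")
  }
  if (response_deadline <= 0) rlang::abort("`response_deadline` must be > 0")
  stopifnot(length(iti_range) == 2L, iti_range[1] <= iti_range[2])
  if (p_choice_error < 0 || p_choice_error > 1) {
    rlang::abort("`p_choice_error` must be in [0, 1]")
  }
  structure(list(n_trials = as.integer(n_trials),
                 n_blocks = as.integer(n_blocks), p_stop = p_stop,
                 ssd_initial = ssd_initial, ssd_step = ssd_step,
                 ssd_min = ssd_min, ssd_max = ssd_max,
                 response_deadline = response_deadline,
                 iti_range = as.numeric(iti_range),
                 p_choice_error = p_choice_error),
            class = "task_design")
}

# Deterministic small-integer stream derivation so any subject/session
# subset of a simulation is reproducible on its own: a splitmix-style hash
# of the master seed and the index path, reduced below 2^31.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- (master %% 2147483647) + 1
  for (k in seq_along(idx)) {
    h <- (h * 48271 + (idx[k] %% 65537) * 1099 + k * 7919) %% 2147483647
  }
  as.integer(h)
}

# fixed per-block stop-trial counts summing to round(n_trials * p_stop)
stop_counts_per_block <- function(design) {
  total <- round(design$n_trials * design$p_stop)
  base <- total %/% design$n_blocks
  extra <- total %% design$n_blocks
  base + as.integer(seq_len(design$n_blocks) <= extra)
}

#' Simulate one stop-signal session
#'
#' Generates a full session of trial records from known race-model
#' parameters under the staircase design: stop trials are scheduled by
#' within-block permutation; go finishing times are drawn from the go
#' runner unless a go failure occurs; responses slower than the deadline
#' are recorded as omissions; on stop trials a response occurs iff the go
#' runner was triggered and either the stop runner failed to trigger or
#' the go finishing time beat SSD + stop finishing time. The SSD starts at
#' `ssd_initial` and moves one `ssd_step` up after every successful stop
#' and down after every failed stop, clamped to `[ssd_min, ssd_max]`.
#'
#' @param design A [task_design()].
#' @param r A [race_params()] object — the generating parameters.
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param subject,condition,session Labels written into the table.
#'
#' @return A tibble with one row per trial: `subject`, `condition`,
#'   `session`, `block`, `trial`, `trial_type`, `ssd`, `response`, `rt`,
#'   `choice_correct`, `iti` (times in seconds; `ssd` is `NA` on go trials,
#'   `rt` is `NA` when there was no response).
#' @examples
#' des <- task_design(n_trials = 90, n_blocks = 9)
#' r <- race_params(go = c(0.87, 0.09, 0.10), stop = c(0.42, 0.04, 0.04))
#' sim <- simulate_session(des, r, seed = 1)
#' table(sim$trial_type)
#' @export
simulate_session <- function(design, r, seed,
                             subject = "s01", condition = "none",
                             session = 1L) {
  stopifnot(inherits(design, "task_design"), inherits(r, "race_params"))
  n <- design$n_trials
  per_block <- n / design$n_blocks
  withr::local_seed(seed)

  counts <- stop_counts_per_block(design)
  is_stop <- logical(n)
  for (b in seq_len(design$n_blocks)) {
    pos <- sample.int(per_block, counts[b])
    is_stop[(b - 1L) * per_block + pos] <- TRUE
  }

  t_go <- rexgauss(n, r$go)
  t_stop <- rexgauss(n, r$stop)
  gf <- stats::runif(n) < r$p_gf
  tf <- stats::runif(n) < r$p_tf
  cerr <- stats::runif(n) < design$p_choice_error
  iti <- stats::runif(n, design$iti_range[1], design$iti_range[2])

  ssd <- rep(NA_real_, n)
  response <- logical(n)
  rt <- rep(NA_real_, n)
  choice_correct <- rep(NA, n)
  cur_ssd <- design$ssd_initial

  for (i in seq_len(n)) {
    if (!is_stop[i]) {
      if (!gf[i] && t_go[i] <= design$response_deadline) {
        response[i] <- TRUE
        rt[i] <- t_go[i]
        choice_correct[i] <- !cerr[i]
      }
    } else {
      ssd[i] <- cur_ssd
      go_started <- !gf[i]
      stop_triggered <- !tf[i]
      races_past_stop <- !stop_triggered || (t_go[i] < cur_ssd + t_stop[i])
      if (go_started && races_past_stop &&
          t_go[i] <= design$response_deadline) {
        response[i] <- TRUE
        rt[i] <- t_go[i]
        # choice accuracy on stop trials is not recorded by the task
      }
      step <- if (response[i]) -design$ssd_step else design$ssd_step
      cur_ssd <- min(max(cur_ssd + step, design$ssd_min), design$ssd_max)
    }
  }

  tibble::tibble(
    subject = subject, condition = condition, session = as.integer(session),
    block = rep(seq_len(design$n_blocks), each = per_block),
    trial = seq_len(n),
    trial_type = ifelse(is_stop, "stop", "go"),
    ssd = ssd, response = response, rt = rt,
    choice_correct = choice_correct, iti = iti
  )
}

#' Group-level (population) parameter specification
#'
#' Location and scale of the group distribution of each of the eight
#' participant-level race-model parameters. Ex-Gaussian parameters are
#' distributed truncated-normal on the seconds scale; trigger-failure and
#' go-failure probabilities are distributed normal on the probit scale
#' (`z_tf`, `z_gf`, with `P = pnorm(z)`).
#'
#' @param location,scale Named numeric vectors over
#'   `c("mu_go","sigma_go","tau_go","mu_stop","sigma_stop","tau_stop",
#'   "z_tf","z_gf")`; scales must be > 0.
#'
#' @return An object of class `population_params`.
#' @seealso [population_defaults()]
#' @export
population_params <- function(location, scale) {
  nm <- race_param_names()
  stopifnot(is.numeric(location), is.numeric(scale))
  if (!all(nm %in% names(location)) || !all(nm %in% names(scale))) {
    rlang::abort(paste("`location` and `scale` must be named over:",
                       paste(nm, collapse = ", ")))
  }
  location <- location[nm]
  scale <- scale[nm]
  if (any(scale < 0)) {
    rlang::abort("population scales must be >= 0 (0 gives a degenerate cohort)")
  }
  structure(list(location = location, scale = scale),
            class = "population_params")
}

race_param_names <- function() {
  c("mu_go", "sigma_go", "tau_go", "mu_stop", "sigma_stop", "tau_stop",
    "z_tf", "z_gf")
}

# participant-level truncation bounds shared by the generator and the priors
race_param_bounds <- function() {
  list(
    lower = c(mu_go = 0.001, sigma_go = 0.001, tau_go = 0.001,
              mu_stop = 0.001, sigma_stop = 0.001, tau_stop = 0.001,
              z_tf = -6, z_gf = -6),
    upper = c(mu_go = 3, sigma_go = 2, tau_go = 2,
              mu_stop = 2, sigma_stop = 2, tau_stop = 2,
              z_tf = 6, z_gf = 6)
  )
}

#' Default population parameters
#'
#' A plausible healthy-adult population for the gamified stop-signal task:
#' group means match typical fitted values (mean go RT near 0.97 s, mean
#' SSRT near 0.46 s, trigger-failure probability near 0.06, omission
#' probability near 0.02); across-subject scales are set to produce
#' subject-to-subject spread comparable to observed descriptive SDs
#' (go RT SD about 0.16 s, SSRT SD about 0.05 s).
#'
#' @return A [population_params()] object.
#' @export
population_defaults <- function() {
  population_params(
    location = c(mu_go = 0.868, sigma_go = 0.099, tau_go = 0.099,
                 mu_stop = 0.411, sigma_stop = 0.036, tau_stop = 0.052,
                 z_tf = stats::qnorm(0.059), z_gf = stats::qnorm(0.018)),
    scale = c(mu_go = 0.12, sigma_go = 0.03, tau_go = 0.04,
              mu_stop = 0.04, sigma_stop = 0.012, tau_stop = 0.02,
              z_tf = 0.35, z_gf = 0.35)
  )
}

# truncated-normal sampler by inverse-CDF (vectorised over n)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# one subject's race_params from pre-drawn quantiles: the design is
# within-subject (every participant serves in every condition), so a
# subject's draw quantiles are fixed once and mapped through each
# condition's population distribution — identical populations then yield
# identical participant parameters across conditions
subject_params_from_quantiles <- function(u, pop) {
  b <- race_param_bounds()
  nm <- race_param_names()
  th <- vapply(seq_along(nm), function(i) {
    k <- nm[i]
    plo <- stats::pnorm(b$lower[[k]], pop$location[[k]], pop$scale[[k]])
    phi <- stats::pnorm(b$upper[[k]], pop$location[[k]], pop$scale[[k]])
    stats::qnorm(plo + u[i] * (phi - plo), pop$location[[k]], pop$scale[[k]])
  }, numeric(1))
  names(th) <- nm
  th
}

theta_to_race_params <- function(th) {
  race_params(
    go = exgauss_params(th[["mu_go"]], th[["sigma_go"]], th[["tau_go"]]),
    stop = exgauss_params(th[["mu_stop"]], th[["sigma_stop"]], th[["tau_stop"]]),
    p_tf = stats::pnorm(th[["z_tf"]]),
    p_gf = stats::pnorm(th[["z_gf"]])
  )
}

#' Simulate a hierarchical cohort
#'
#' Draws participant-level race parameters from group distributions
#' (truncated-normal for the ex-Gaussian parameters, probit-normal for the
#' failure probabilities) and simulates one session per subject and
#' condition. The design is within-subject: each participant's draw
#' quantiles are fixed once and mapped through every condition's
#' population, so identical populations produce identical participant
#' parameters across conditions and condition effects act on a common
#' cohort. Per-subject random streams are derived deterministically from
#' the master seed, so any subset of the cohort is reproducible.
#'
#' @param n_subjects Number of subjects.
#' @param populations A single [population_params()] (shared by all
#'   conditions) or a named list, one per condition.
#' @param design A [task_design()].
#' @param seed Master integer seed.
#' @param conditions Character vector of condition labels; defaults to the
#'   names of `populations` or `"cond1"`.
#'
#' @return A list with `trials` (one tibble, `n_subjects x conditions x
#'   n_trials` rows) and `params` (a tibble of the true participant-level
#'   parameters, one row per subject x condition, with `p_tf`/`p_gf` on
#'   the probability scale alongside `z_tf`/`z_gf`).
#' @examples
#' des <- task_design(n_trials = 45, n_blocks = 9)
#' cohort <- simulate_cohort(3, population_defaults(), des, seed = 7)
#' dplyr::count(cohort$trials, condition, trial_type)
#' @export
simulate_cohort <- function(n_subjects, populations, design, seed,
                            conditions = NULL) {
  stopifnot(n_subjects >= 1, inherits(design, "task_design"))
  if (inherits(populations, "population_params")) {
    if (is.null(conditions)) conditions <- "cond1"
    populations <- stats::setNames(
      rep(list(populations), length(conditions)), conditions)
  } else {
    stopifnot(is.list(populations),
              all(vapply(populations, inherits, logical(1),
                         "population_params")))
    if (is.null(conditions)) conditions <- names(populations)
    stopifnot(length(conditions) == length(populations))
    names(populations) <- conditions
  }

  subjects <- sprintf("s%02d", seq_len(n_subjects))
  quantiles <- lapply(seq_len(n_subjects), function(si) {
    withr::with_seed(derive_seed(seed, 0L, si, 1L), stats::runif(8))
  })
  out_trials <- vector("list", n_subjects * length(conditions))
  out_params <- vector("list", n_subjects * length(conditions))
  k <- 0L
  for (ci in seq_along(conditions)) {
    for (si in seq_len(n_subjects)) {
      k <- k + 1L
      th <- subject_params_from_quantiles(quantiles[[si]], populations[[ci]])
      r <- theta_to_race_params(th)
      out_trials[[k]] <- simulate_session(
        design, r, seed = derive_seed(seed, ci, si, 2L),
        subject = subjects[si], condition = conditions[ci], session = ci)
      out_params[[k]] <- tibble::tibble(
        subject = subjects[si], condition = conditions[ci],
        !!!as.list(th), p_tf = r$p_tf, p_gf = r$p_gf)
    }
  }
  list(trials = dplyr::bind_rows(out_trials),
       params = dplyr::bind_rows(out_params))
}
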