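#' Prior specification for the hierarchical race model
#'
#' Weakly informative priors restricting all parameters to a plausible
#' range. Participant-level ex-Gaussian parameters follow
#' Normal(location, scale) distributions truncated to `[0.001, 2]` s
#' (`mu_go` to `[0.001, 3]` s); the probit-scale failure parameters
#' `z_tf`, `z_gf` follow Normals truncated to `[-6, 6]`. Hyper-locations
#' are Uniform over the same bounds and hyper-scales Uniform over
#' `[0.001, 1]`.
#'
#' @param lower,upper Optional named overrides of the participant-level
#'   truncation bounds.
#' @param scale_upper Upper bound of the Uniform hyperprior on group
#'   scales.
#'
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(lower = NULL, upper = NULL, scale_upper = 1) {
  b <- race_param_bounds()
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  if (any(b$upper <= b$lower)) rlang::abort("bounds must satisfy lower < upper")
  if (scale_upper <= 0.001) rlang::abort("`scale_upper` must exceed 0.001")
  structure(list(lower = b$lower, upper = b$upper,
                 scale_lower = 0.001, scale_upper = scale_upper),
            class = "prior_spec")
}

# log of the truncated-normal density, vectorised over x
log_dtnorm <- function(x, mean, sd, lower, upper) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  out <- stats::dnorm(x, mean, sd, log = TRUE) - log(z)
  out[x < lower | x > upper] <- -Inf
  out
}

# drop responded go trials with a wrong-side choice before model fitting
reduce_for_fit <- function(trials) {
  bad <- trials$trial_type == "go" & trials$response &
    isFALSE_vec(trials$choice_correct)
  trials[!bad, , drop = FALSE]
}

# trials tibble -> per-subject sufficient-statistic lists for the C++ kernel
prepare_fit_data <- function(trials) {
  trials <- reduce_for_fit(trials)
  split(trials, trials$subject) |>
    lapply(condition_data)
}

# participant-level params on the sampler scale, with z_tf/z_gf probit
theta_for_loglik <- function(theta) {
  c(theta[1:6], stats::pnorm(theta[7]), stats::pnorm(theta[8]))
}

#' Hierarchical log posterior
#'
#' Joint log density of participant-level and population-level parameters
#' given one condition's trial data: the sum of race-model trial
#' log-likelihoods, the truncated-normal (ex-Gaussian parameters) and
#' probit-normal (`z_tf`, `z_gf`) group densities, and the uniform
#' hyperpriors. Out-of-bound parameters return the floor value.
#'
#' @param trials Trial table for one condition (choice-error go trials are
#'   removed internally), seconds.
#' @param participant A numeric matrix, one row per subject (ordered as
#'   `sort(unique(trials$subject))`), columns
#'   `mu_go, sigma_go, tau_go, mu_stop, sigma_stop, tau_stop, z_tf, z_gf`.
#' @param population A list with numeric `location` and `scale`, each
#'   named over the same eight parameters.
#' @param priors A [prior_spec()].
#' @param floor Value returned for out-of-bound parameter sets.
#'
#' @return A single log-density value.
#' @export
log_posterior <- function(trials, participant, population,
                          priors = prior_spec(), floor = -1e10) {
  dat <- prepare_fit_data(trials)
  stopifnot(is.matrix(participant), nrow(participant) == length(dat),
            ncol(participant) == 8L)
  loc <- population$location[race_param_names()]
  sc <- population$scale[race_param_names()]
  if (any(loc < priors$lower) || any(loc > priors$upper) ||
      any(sc < priors$scale_lower) || any(sc > priors$scale_upper)) {
    return(floor)
  }
  ll <- 0
  for (j in seq_along(dat)) {
    th <- participant[j, ]
    if (any(th < priors$lower) || any(th > priors$upper)) return(floor)
    ll <- ll + subject_loglik_cpp(dat[[j]], theta_for_loglik(th))
    ll <- ll + sum(log_dtnorm(th, loc, sc, priors$lower, priors$upper))
  }
  if (!is.finite(ll)) floor else ll
}

# default random-walk proposal scales (pre-adaptation), sampler scale
subject_proposal_base <- function() {
  c(mu_go = 0.012, sigma_go = 0.008, tau_go = 0.012,
    mu_stop = 0.030, sigma_stop = 0.020, tau_stop = 0.025,
    z_tf = 0.40, z_gf = 0.40)
}

# moment-based initial values for one subject
init_subject <- function(dat, priors) {
  grt <- dat$go_rt
  if (length(grt) < 2) {
    # no usable go data (e.g. prior-only runs): mid-range defaults
    th <- c(mu_go = 0.8, sigma_go = 0.1, tau_go = 0.1,
            mu_stop = 0.3, sigma_stop = 0.05, tau_stop = 0.05,
            z_tf = -1.5, z_gf = -2)
    return(pmin(pmax(th, priors$lower + 1e-3), priors$upper - 1e-3))
  }
  m <- mean(grt); s <- stats::sd(grt)
  if (!is.finite(s) || s <= 0) s <- 0.1
  sk <- mean((grt - m)^3) / s^3
  tau <- max(0.02, min(s * (max(sk, 0.1) / 2)^(1 / 3), s * 0.95, 0.5))
  mu <- max(m - tau, 0.1)
  sig <- sqrt(max(s^2 - tau^2, 1e-4))
  # crude stop init from the responding rate and signal-respond RTs
  n_st <- length(dat$sr_rt) + sum(dat$inhib_n)
  mean_ssd <- if (n_st > 0) {
    stats::weighted.mean(c(dat$sr_ssd, dat$inhib_ssd),
                         c(rep(1, length(dat$sr_ssd)), dat$inhib_n))
  } else 0.25
  ssrt0 <- max(m - mean_ssd, 0.15)
  p_omit <- dat$n_go_omit / max(dat$n_go_omit + length(grt), 1)
  th <- c(mu_go = mu, sigma_go = sig, tau_go = tau,
          mu_stop = max(ssrt0 - 0.05, 0.1), sigma_stop = 0.05,
          tau_stop = 0.05,
          z_tf = stats::qnorm(0.05),
          z_gf = stats::qnorm(min(max(p_omit, 0.005), 0.3)))
  pmin(pmax(th, priors$lower + 1e-3), priors$upper - 1e-3)
}

#' Fit the hierarchical trigger-failure race model
#'
#' Samples the joint posterior of participant- and population-level
#' parameters for one condition by blocked adaptive random-walk
#' Metropolis-within-Gibbs: each subject's eight parameters are updated
#' as one block against the race-model likelihood and the group prior,
#' then each population (location, scale) pair is updated against the
#' group density and the uniform hyperpriors. Proposal scales adapt
#' during burn-in (targeting ~25% acceptance, with component scales
#' following the running posterior spread) and are frozen afterwards.
#'
#' @param trials Trial table for a single condition, seconds. Choice-error
#'   go trials are removed before fitting.
#' @param priors A [prior_spec()].
#' @param chains Number of chains (run sequentially).
#' @param iter Total iterations per chain, including burn-in.
#' @param burn Burn-in iterations discarded (and used for adaptation).
#' @param seed Integer seed; fits are exactly reproducible.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param progress Print a progress line per chain?
#'
#' @return An object of class `beests_fit`: draws as an
#'   `iterations x chains x parameters` array (population
#'   `<param>_loc` / `<param>_scale`, then `<param>[subject]`), plus
#'   acceptance rates, settings and data summaries. Use
#'   [summarise_posterior()], [rhat()], [tidy()][generics::tidy],
#'   [posterior_predictive()].
#' @export
fit_beests <- function(trials, priors = prior_spec(), chains = 3,
                       iter = 5000, burn = 2500, seed = 1, thin = 1,
                       progress = FALSE) {
  stopifnot(burn < iter, chains >= 1)
  cond <- unique(trials$condition)
  if (length(cond) > 1) {
    rlang::abort("fit one condition at a time (the model is estimated separately per condition)")
  }
  dat <- prepare_fit_data(trials)
  subjects <- names(dat)
  n_subj <- length(subjects)
  single_subject <- n_subj < 2

  nm <- race_param_names()
  par_names <- c(paste0(nm, "_loc"), paste0(nm, "_scale"),
                 as.vector(t(outer(nm, subjects,
                                   function(p, s) paste0(p, "[", s, "]")))))
  n_keep <- floor((iter - burn) / thin)
  draws <- array(NA_real_,
                 dim = c(n_keep, chains, length(par_names)),
                 dimnames = list(iteration = NULL,
                                 chain = paste0("chain", seq_len(chains)),
                                 parameter = par_names))
  acc <- matrix(0, chains, n_subj + 8,
                dimnames = list(NULL, c(subjects, paste0("pop_", nm))))

  inits <- lapply(dat, init_subject, priors = priors)
  init_mat <- do.call(rbind, inits)

  for (ch in seq_len(chains)) {
    res <- run_chain(dat, priors, init_mat, iter, burn, thin, n_keep,
                     seed = derive_seed(seed, 9000L + ch),
                     jitter = 0.5 * (ch - 1) / max(chains - 1, 1),
                     single_subject = single_subject)
    draws[, ch, ] <- res$draws
    acc[ch, ] <- res$acc
    if (progress) {
      message(sprintf("chain %d/%d done (mean acceptance %.2f)",
                      ch, chains, mean(res$acc)))
    }
  }

  structure(list(
    draws = draws, acceptance = acc, subjects = subjects,
    condition = if (length(cond)) cond else NA_character_,
    priors = priors,
    settings = list(chains = chains, iter = iter, burn = burn,
                    thin = thin, seed = seed),
    n_trials = nrow(trials),
    single_subject = single_subject
  ), class = "beests_fit")
}

# One MCMC chain, delegated to the compiled sampler: subject blocks,
# population (location, scale) blocks, and the translation and
# scale-expansion ridge moves that mix the weakly identified stop-side
# hierarchy. Initial values are jittered per chain here so chains start
# overdispersed.
run_chain <- function(dat, priors, init_mat, iter, burn, thin, n_keep,
                      seed, jitter, single_subject) {
  withr::local_seed(seed)
  nm <- race_param_names()
  n_subj <- length(dat)
  lower <- priors$lower; upper <- priors$upper

  theta <- init_mat * (1 + 0.02 * jitter) +
    matrix(stats::rnorm(n_subj * 8, 0,
                        jitter * c(rep(0.02, 6), 0.15, 0.15)),
           n_subj, 8, byrow = TRUE)
  theta <- sweep(theta, 2, lower + 1e-4, pmax)
  theta <- sweep(theta, 2, upper - 1e-4, pmin)
  colnames(theta) <- nm

  loc <- colMeans(theta)
  sc <- pmax(apply(theta, 2, stats::sd), 0.02)
  sc <- pmin(pmax(sc, priors$scale_lower + 1e-4),
             priors$scale_upper - 1e-4)
  if (single_subject) sc <- pmin(subject_proposal_base() * 5, 0.9)

  res <- run_chain_cpp(
    dat = unname(dat), init_theta = unname(theta),
    lower = unname(lower), upper = unname(upper),
    scale_lower = priors$scale_lower, scale_upper = priors$scale_upper,
    init_loc = unname(loc), init_sc = unname(sc),
    iter = as.integer(iter), burn = as.integer(burn),
    thin = as.integer(thin), n_keep = as.integer(n_keep),
    shift_idx = c(5L, 6L, 7L),        # sigma_stop, tau_stop, z_tf
    expand_idx = c(5L, 6L, 7L),       # sigma_stop, tau_stop, z_tf
    single_subject = single_subject, n_nodes = 48L)
  list(draws = res$draws, acc = res$acc)
}
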