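#' Race-model parameters for one participant in one condition
#'
#' Bundles the generative parameter set of the independent horse-race model
#' with trigger failures: the ex-Gaussian finishing-time distributions of
#' the go and stop runners, the probability `p_tf` that the stop runner is
#' never triggered on a stop trial, and the probability `p_gf` that the go
#' runner is never triggered (producing an omission).
#'
#' @param go,stop [exgauss_params()] objects (or numeric `c(mu, sigma, tau)`).
#' @param p_tf Stop trigger-failure probability, in `[0, 1]`.
#' @param p_gf Go failure probability, in `[0, 1]`.
#'
#' @return An object of class `race_params`.
#' @examples
#' r <- race_params(go = c(0.87, 0.10, 0.10), stop = c(0.41, 0.04, 0.05))
#' p_respond_given_ssd(r, ssd = 0.25)
#' @export
race_params <- function(go, stop, p_tf = 0, p_gf = 0) {
  go <- as_exgauss(go)
  stop <- as_exgauss(stop)
  stopifnot(is.numeric(p_tf), length(p_tf) == 1L,
            is.numeric(p_gf), length(p_gf) == 1L)
  if (p_tf < 0 || p_tf > 1) rlang::abort("`p_tf` must be in [0, 1]")
  if (p_gf < 0 || p_gf > 1) rlang::abort("`p_gf` must be in [0, 1]")
  structure(list(go = go, stop = stop, p_tf = p_tf, p_gf = p_gf),
            class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model parameters (seconds):\n")
  cat(sprintf("  go:   mu = %.3f, sigma = %.3f, tau = %.3f\n",
              x$go[["mu"]], x$go[["sigma"]], x$go[["tau"]]))
  cat(sprintf("  stop: mu = %.3f, sigma = %.3f, tau = %.3f\n",
              x$stop[["mu"]], x$stop[["sigma"]], x$stop[["tau"]]))
  cat(sprintf("  P(TF) = %.3f, P(GF) = %.3f\n", x$p_tf, x$p_gf))
  invisible(x)
}

# integration range covering the go density to ~1e-9 tail mass
go_support <- function(go) {
  c(go[["mu"]] - 8 * go[["sigma"]],
    go[["mu"]] + 8 * go[["sigma"]] + 22 * go[["tau"]])
}

#' Probability of responding on a stop trial
#'
#' Under the independent race model with trigger failures, a response
#' occurs on a stop trial when the go runner is triggered and either the
#' stop runner fails to trigger or the go finishing time beats
#' SSD + stop finishing time:
#' \deqn{P(\mathrm{respond} \mid \mathrm{SSD}) = (1 - P_{GF})\left[P_{TF} +
#'   (1 - P_{TF}) \int f_{go}(t)\,\{1 - F_{stop}(t - \mathrm{SSD})\}\,dt\right].}
#' The integral has no closed form for ex-Gaussian runners and is computed
#' by adaptive quadrature on the truncated go support (absolute tolerance
#' 1e-9).
#'
#' @param r A [race_params()] object.
#' @param ssd Stop-signal delay(s), seconds; vectorised.
#'
#' @return Probabilities, one per `ssd`; nondecreasing in `ssd` and bounded
#'   above by `1 - p_gf`.
#' @export
p_respond_given_ssd <- function(r, ssd) {
  stopifnot(inherits(r, "race_params"), is.numeric(ssd), all(is.finite(ssd)))
  sup <- go_support(r$go)
  vapply(ssd, function(d) {
    q <- stats::integrate(
      function(t) dexgauss(t, r$go) * (1 - pexgauss(t - d, r$stop)),
      lower = sup[1], upper = sup[2],
      abs.tol = 1e-9, rel.tol = 1e-9, subdivisions = 400L)
    if (q$message != "OK") {
      rlang::abort(sprintf(
        "race quadrature failed at ssd = %g: %s (abs.error %g)",
        d, q$message, q$abs.error))
    }
    p <- (1 - r$p_gf) * (r$p_tf + (1 - r$p_tf) * min(max(q$value, 0), 1))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Log density of a signal-respond reaction time
#'
#' Density of an executed response at time `t` on a stop trial with the
#' given stop-signal delay: the go runner finishes at `t` and either the
#' stop runner never triggered or it finishes after `t`. This density is
#' defective — it integrates to `p_respond_given_ssd()`, not to 1.
#'
#' @param t Response time(s), seconds; vectorised.
#' @inheritParams p_respond_given_ssd
#' @param floor Log-density floor returned where the density is zero
#'   (impossible outcomes); keeps MCMC rejection smooth. Use `-Inf` to
#'   disable.
#'
#' @return Log densities, one per `t`.
#' @export
signal_respond_logdensity <- function(t, r, ssd, floor = -700) {
  stopifnot(inherits(r, "race_params"))
  mix <- r$p_tf + (1 - r$p_tf) * (1 - pexgauss(t - ssd, r$stop))
  out <- log1p(-r$p_gf) + dexgauss(t, r$go, log = TRUE) + log(mix)
  pmax(out, floor)
}

#' Log likelihood of a single trial
#'
#' Evaluates the race-model log likelihood of one trial record:
#' a responded go trial contributes `(1 - p_gf) f_go(rt)`; a go omission
#' `p_gf`; a responded stop trial the [signal_respond_logdensity()]; an
#' inhibited stop trial `1 - p_respond_given_ssd()`.
#'
#' @param trial A one-row data frame (or list) with fields `trial_type`
#'   (`"go"` or `"stop"`), `response` (logical), `rt` (seconds, `NA` when
#'   no response) and `ssd` (seconds, `NA` on go trials).
#' @inheritParams signal_respond_logdensity
#'
#' @return A single log-likelihood value (floored per trial).
#' @export
trial_loglik <- function(trial, r, floor = -700) {
  stopifnot(inherits(r, "race_params"))
  type <- as.character(trial$trial_type)
  responded <- isTRUE(as.logical(trial$response))
  rt <- trial$rt
  ssd <- trial$ssd
  if (!type %in% c("go", "stop")) {
    rlang::abort(sprintf("unknown trial_type %s", type))
  }
  if (responded && (is.null(rt) || is.na(rt))) {
    rlang::abort("responded trial without an rt")
  }
  if (!responded && !is.null(rt) && !is.na(rt)) {
    rlang::abort("rt present on a trial without a response")
  }
  if (type == "go" && !is.null(ssd) && !is.na(ssd)) {
    rlang::abort("ssd present on a go trial")
  }
  if (type == "stop" && (is.null(ssd) || is.na(ssd))) {
    rlang::abort("stop trial without an ssd")
  }
  ll <- if (type == "go") {
    if (responded) log1p(-r$p_gf) + dexgauss(rt, r$go, log = TRUE)
    else log(r$p_gf)
  } else {
    if (responded) signal_respond_logdensity(rt, r, ssd, floor = -Inf)
    else log(1 - p_respond_given_ssd(r, ssd))
  }
  max(ll, floor)
}

#' Log likelihood of a trial table
#'
#' Sums [trial_loglik()] over the rows of a trial table for a single
#' participant and condition, using the vectorised compiled kernel. Equal
#' (to numerical tolerance) to summing `trial_loglik()` row by row.
#'
#' @param trials A trial table (see [read_trials()] for the schema) for one
#'   subject in one condition, times in seconds.
#' @inheritParams signal_respond_logdensity
#'
#' @return A single log-likelihood value.
#' @export
table_loglik <- function(trials, r, floor = -700) {
  stopifnot(inherits(r, "race_params"))
  dat <- condition_data(trials)
  theta <- c(r$go, r$stop, r$p_tf, r$p_gf)
  subject_loglik_cpp(dat, as.numeric(theta), floor_val = floor)
}

# Reduce one subject-condition trial table to the sufficient pieces the
# compiled likelihood consumes. Inhibited stop trials are grouped by unique
# SSD so the race integral is evaluated once per delay.
condition_data <- function(trials) {
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  st <- trials[trials$trial_type == "stop", , drop = FALSE]
  sr <- st[st$response, , drop = FALSE]
  inh <- st[!st$response, , drop = FALSE]
  tab <- table(inh$ssd)
  list(
    go_rt = as.numeric(go$rt[go$response]),
    n_go_omit = sum(!go$response),
    sr_rt = as.numeric(sr$rt),
    sr_ssd = as.numeric(sr$ssd),
    inhib_ssd = as.numeric(names(tab)),
    inhib_n = as.integer(tab)
  )
}
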