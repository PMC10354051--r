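#' Ex-Gaussian finishing-time parameters
#'
#' Constructs and validates the parameter triplet of an ex-Gaussian
#' distribution, the convolution of a Normal(`mu`, `sigma`) with an
#' Exponential of mean `tau`. The ex-Gaussian is the standard parametric
#' model for response-time distributions: `mu` and `sigma` describe the
#' Gaussian body, `tau` the slow exponential tail. Its mean is `mu + tau`
#' and its variance `sigma^2 + tau^2`. All values are in seconds.
#'
#' @param mu Mean of the Gaussian component (seconds).
#' @param sigma Standard deviation of the Gaussian component (seconds, > 0).
#' @param tau Mean of the exponential component (seconds, > 0).
#'
#' @return An object of class `exgauss_params`: a named numeric vector
#'   `c(mu, sigma, tau)`.
#' @examples
#' p <- exgauss_params(mu = 0.5, sigma = 0.1, tau = 0.1)
#' dexgauss(0.6, p)
#' @export
exgauss_params <- function(mu, sigma, tau) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(tau),
            length(mu) == 1L, length(sigma) == 1L, length(tau) == 1L)
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(tau)) {
    stop("ex-Gaussian parameters must be finite", call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  structure(c(mu = mu, sigma = sigma, tau = tau), class = "exgauss_params")
}

as_exgauss <- function(p) {
  if (inherits(p, "exgauss_params")) return(p)
  if (is.numeric(p) && length(p) == 3L) {
    return(exgauss_params(p[[1L]], p[[2L]], p[[3L]]))
  }
  stop("expected an `exgauss_params` object or a numeric (mu, sigma, tau)",
       call. = FALSE)
}

#' @export
print.exgauss_params <- function(x, ...) {
  cat(sprintf("ex-Gaussian(mu = %.4g, sigma = %.4g, tau = %.4g) s  [mean %.4g s]\n",
              x[["mu"]], x[["sigma"]], x[["tau"]], x[["mu"]] + x[["tau"]]))
  invisible(x)
}

#' Ex-Gaussian density, distribution function and random deviates
#'
#' `dexgauss()` evaluates the ex-Gaussian probability density,
#' `pexgauss()` the cumulative distribution function, `qexgauss()` the
#' quantile function (by monotone root-finding on `pexgauss()`), and
#' `rexgauss()` draws random deviates as Normal plus Exponential.
#'
#' The density is computed in log space — the exponential factor and the
#' Gaussian tail probability are combined before exponentiation — so that
#' values remain finite and accurate when `tau` is small relative to
#' `sigma`, where the naive product overflows.
#'
#' @param x,q Vector of quantiles (seconds).
#' @param p Vector of probabilities (for `qexgauss()`).
#' @param params An [exgauss_params()] object (or numeric `c(mu, sigma, tau)`).
#' @param n Number of deviates.
#' @param log,log.p Logical: return log density / log probability?
#'
#' @return `dexgauss()` a density per second; `pexgauss()` a probability;
#'   `qexgauss()` a quantile in seconds; `rexgauss()` `n` deviates.
#' @examples
#' p <- exgauss_params(0.5, 0.1, 0.1)
#' pexgauss(qexgauss(0.5, p), p)  # 0.5
#' mean(rexgauss(1e4, p))         # close to mu + tau = 0.6
#' @export
dexgauss <- function(x, params, log = FALSE) {
  params <- as_exgauss(params)
  lp <- exg_logpdf_cpp(as.numeric(x), params[["mu"]], params[["sigma"]],
                       params[["tau"]])
  if (log) lp else exp(lp)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, params, log.p = FALSE) {
  params <- as_exgauss(params)
  pr <- exg_cdf_cpp(as.numeric(q), params[["mu"]], params[["sigma"]],
                    params[["tau"]])
  if (log.p) log(pr) else pr
}

#' @rdname dexgauss
#' @export
qexgauss <- function(p, params, lower = NULL, upper = NULL) {
  params <- as_exgauss(params)
  stopifnot(all(p > 0 & p < 1))
  mu <- params[["mu"]]; sigma <- params[["sigma"]]; tau <- params[["tau"]]
  if (is.null(lower)) lower <- mu - 10 * sigma
  if (is.null(upper)) upper <- mu + 10 * sigma + 50 * tau
  vapply(p, function(pp) {
    stats::uniroot(function(t) pexgauss(t, params) - pp,
                   lower = lower, upper = upper, tol = 1e-10)$root
  }, numeric(1))
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, params) {
  params <- as_exgauss(params)
  stopifnot(n >= 1)
  stats::rnorm(n, params[["mu"]], params[["sigma"]]) +
    stats::rexp(n, rate = 1 / params[["tau"]])
}
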