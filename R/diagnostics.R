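#' Gelman-Rubin convergence diagnostics
#'
#' Potential scale-reduction factors for a fitted model (or a raw
#' `iterations x chains x parameters` draws array): per parameter the
#' classic between/within-chain variance ratio
#' \deqn{\hat{R} = \sqrt{\frac{(n-1)/n\,W + B/n}{W}},}
#' and the multivariate (Brooks-Gelman) factor computed over the
#' population-level parameters. Convergence is declared when every
#' univariate factor and the multivariate factor are below `threshold`.
#'
#' @param x A `beests_fit` or a 3-d draws array.
#' @param threshold Convergence threshold (default 1.1).
#'
#' @return A tibble with one row per parameter (`parameter`, `rhat`) and
#'   attributes `multivariate` (the multivariate factor) and `converged`.
#' @export
rhat <- function(x, threshold = 1.1) {
  draws <- if (inherits(x, "beests_fit")) x$draws else x
  stopifnot(length(dim(draws)) == 3L)
  m <- dim(draws)[2]
  if (m < 2) rlang::abort("R-hat needs at least 2 chains")
  n <- dim(draws)[1]
  pars <- dimnames(draws)[[3]]
  if (is.null(pars)) pars <- paste0("par", seq_len(dim(draws)[3]))

  uni <- vapply(seq_len(dim(draws)[3]), function(p) {
    ch <- draws[, , p, drop = TRUE]
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = m)
    w <- mean(apply(ch, 2, stats::var))
    b <- n * stats::var(colMeans(ch))
    if (w <= 0) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))

  # multivariate factor over the population block when names identify it,
  # else over all parameters
  pop_idx <- grep("_(loc|scale)$", pars)
  if (length(pop_idx) == 0) pop_idx <- seq_along(pars)
  mv <- multivariate_psrf(draws[, , pop_idx, drop = FALSE])

  out <- tibble::tibble(parameter = pars, rhat = uni)
  attr(out, "multivariate") <- mv
  attr(out, "converged") <- all(uni < threshold) && mv < threshold
  out
}

multivariate_psrf <- function(draws) {
  n <- dim(draws)[1]; m <- dim(draws)[2]; p <- dim(draws)[3]
  chains <- lapply(seq_len(m), function(ch) draws[, ch, , drop = TRUE])
  chains <- lapply(chains, function(x) if (is.null(dim(x))) matrix(x) else x)
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  mns <- do.call(rbind, lapply(chains, colMeans))
  B_n <- stats::cov(mns)  # = B/n
  W <- W + diag(1e-10, p)
  lam <- tryCatch(
    max(Re(eigen(solve(W, B_n), only.values = TRUE)$values)),
    error = function(e) NA_real_)
  if (!is.finite(lam)) return(NA_real_)
  sqrt((n - 1) / n + (m + 1) / m * lam)
}
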