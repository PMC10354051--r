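#' Posterior draws as a tidy tibble
#'
#' Collapses the chains of a fitted model into a long-format-ready wide
#' tibble: one row per chain x iteration, one column per parameter,
#' preceded by `chain` and `iteration` columns.
#'
#' @param fit A `beests_fit`.
#' @return A tibble.
#' @export
tidy_draws <- function(fit) {
  stopifnot(inherits(fit, "beests_fit"))
  d <- fit$draws
  n <- dim(d)[1]; m <- dim(d)[2]
  flat <- do.call(rbind, lapply(seq_len(m), function(ch) {
    matrix(d[, ch, ], nrow = n, ncol = dim(d)[3])
  }))
  colnames(flat) <- dimnames(d)[[3]]
  dplyr::bind_cols(
    tibble::tibble(chain = rep(seq_len(m), each = n),
                   iteration = rep(seq_len(n), m)),
    tibble::as_tibble(flat))
}

#' Posterior summary with 95% credible intervals
#'
#' Posterior means and central credible intervals (2.5th and 97.5th
#' percentiles of the pooled post-burn-in draws) per parameter, on the
#' reporting scale: seconds for the ex-Gaussian parameters, and for the
#' probit-scale failure parameters additional probability-scale rows
#' (`p_tf*`, `p_gf*`) obtained by applying the inverse probit to every
#' draw before averaging.
#'
#' @param fit A `beests_fit` (or a draws tibble from [tidy_draws()]).
#' @param level Credible level (default 0.95).
#'
#' @return A tibble: `parameter`, `mean`, `lower`, `upper`.
#' @export
summarise_posterior <- function(fit, level = 0.95) {
  draws <- if (inherits(fit, "beests_fit")) tidy_draws(fit) else fit
  pars <- setdiff(names(draws), c("chain", "iteration"))
  alpha <- (1 - level) / 2
  base <- purrr::map_dfr(pars, function(p) {
    x <- draws[[p]]
    q <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE)
    tibble::tibble(parameter = p, mean = mean(x), lower = q[1], upper = q[2])
  })
  z_pars <- grep("^z_(tf|gf)", pars, value = TRUE)
  prob <- purrr::map_dfr(z_pars, function(p) {
    x <- stats::pnorm(draws[[p]])
    q <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE)
    tibble::tibble(parameter = sub("^z_", "p_", p),
                   mean = mean(x), lower = q[1], upper = q[2])
  })
  dplyr::bind_rows(base, prob)
}

#' Posterior of a derived finishing-time mean (mu + tau)
#'
#' The mean of an ex-Gaussian finishing-time distribution is `mu + tau`,
#' so the posterior of the mean go RT or mean SSRT is obtained by summing
#' the `mu` and `tau` draws on each iteration and collapsing across
#' chains.
#'
#' @param fit A `beests_fit`, or a draws tibble containing columns
#'   `mu_<which>_loc` and `tau_<which>_loc` (population level).
#' @param which `"go"` (mean correct go RT) or `"stop"` (mean SSRT).
#' @param level `"population"` (group locations) or a subject id.
#'
#' @return A numeric vector of posterior draws of `mu + tau`, chains
#'   collapsed, in seconds.
#' @examples
#' draws <- tibble::tibble(mu_stop_loc = c(0.41, 0.42),
#'                         tau_stop_loc = c(0.05, 0.06))
#' derived_mean_posterior(draws, "stop")
#' @export
derived_mean_posterior <- function(fit, which = c("go", "stop"),
                                   level = "population") {
  which <- match.arg(which)
  draws <- if (inherits(fit, "beests_fit")) tidy_draws(fit) else fit
  suffix <- if (identical(level, "population")) "_loc"
            else paste0("[", level, "]")
  mu_col <- paste0("mu_", which, suffix)
  tau_col <- paste0("tau_", which, suffix)
  if (!all(c(mu_col, tau_col) %in% names(draws))) {
    rlang::abort(sprintf("draws do not contain %s and %s", mu_col, tau_col))
  }
  mu <- draws[[mu_col]]; tau <- draws[[tau_col]]
  if (length(mu) != length(tau)) {
    rlang::abort("mu and tau draw vectors are misaligned")
  }
  as.numeric(mu + tau)
}

#' Bayesian p-value between two posteriors
#'
#' The proportion of posterior samples in `draws_a` that exceed the
#' corresponding samples in `draws_b`. With `method = "paired"` (default)
#' draws are compared by iteration index, which matches how independently
#' fitted conditions are conventionally compared; `"pooled"` compares all
#' cross-pairs. Ties count 0.5, so `bayesian_p(a, b) + bayesian_p(b, a)`
#' is always 1.
#'
#' @param draws_a,draws_b Non-empty numeric draw vectors (equal length for
#'   the paired method).
#' @param method `"paired"` or `"pooled"`.
#' @return A probability.
#' @export
bayesian_p <- function(draws_a, draws_b,
                       method = c("paired", "pooled")) {
  method <- match.arg(method)
  if (length(draws_a) == 0 || length(draws_b) == 0) {
    rlang::abort("draw vectors must be non-empty")
  }
  if (method == "paired") {
    if (length(draws_a) != length(draws_b)) {
      rlang::abort("paired comparison needs equal-length draw vectors")
    }
    mean(draws_a > draws_b) + 0.5 * mean(draws_a == draws_b)
  } else {
    sb <- sort(draws_b)
    n_lt <- findInterval(draws_a, sb, left.open = TRUE)   # b < a
    n_le <- findInterval(draws_a, sb)                     # b <= a
    mean((n_lt + 0.5 * (n_le - n_lt)) / length(sb))
  }
}

#' Pairwise condition comparison
#'
#' Computes pairwise Bayesian p-values between independently fitted
#' conditions for the four headline quantities: mean SSRT
#' (`mu_stop + tau_stop`), mean correct go RT (`mu_go + tau_go`),
#' P(TF) and P(GF) (population locations, probability scale). Draws are
#' collapsed across chains and paired by iteration index; fits with
#' unequal draw counts are truncated to the shortest.
#'
#' @param fits A named list of `beests_fit` objects, one per condition
#'   (same sampler settings); names are the condition labels.
#'
#' @return An object of class `beests_comparison`: a list with `bp`
#'   (tibble: `parameter`, `condition_a`, `condition_b`, `bp`) and
#'   `draws` (long tibble of the compared posterior draws, used by
#'   `autoplot()`).
#' @export
compare_conditions <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$condition, character(1))
  }
  qty <- function(fit) {
    td <- tidy_draws(fit)
    tibble::tibble(
      ssrt = derived_mean_posterior(td, "stop"),
      go_rt = derived_mean_posterior(td, "go"),
      p_tf = stats::pnorm(td$z_tf_loc),
      p_gf = stats::pnorm(td$z_gf_loc))
  }
  qdraws <- purrr::map(fits, qty)
  n_min <- min(vapply(qdraws, nrow, integer(1)))
  if (length(unique(vapply(qdraws, nrow, integer(1)))) > 1) {
    rlang::warn("fits differ in draw count; truncating to the shortest")
  }
  qdraws <- purrr::map(qdraws, ~ .x[seq_len(n_min), ])

  conds <- names(fits)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  bp <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(c("ssrt", "go_rt", "p_tf", "p_gf"), function(p) {
      tibble::tibble(parameter = p, condition_a = pr[1],
                     condition_b = pr[2],
                     bp = bayesian_p(qdraws[[pr[1]]][[p]],
                                     qdraws[[pr[2]]][[p]]))
    })
  })
  long <- purrr::imap_dfr(qdraws, function(d, cond) {
    tidyr::pivot_longer(dplyr::mutate(d, condition = cond,
                                      .draw = dplyr::row_number()),
                        cols = c("ssrt", "go_rt", "p_tf", "p_gf"),
                        names_to = "parameter", values_to = "value")
  })
  structure(list(bp = bp, draws = long), class = "beests_comparison")
}

#' @export
print.beests_comparison <- function(x, ...) {
  cat("Pairwise Bayesian p-values (P[draws_a > draws_b]):\n")
  print(dplyr::mutate(x$bp, bp = round(.data$bp, 3)), n = Inf)
  invisible(x)
}

#' Overlaid posterior densities per condition
#'
#' Density overlays of the population-level posteriors of mean SSRT and
#' mean correct go RT (milliseconds) and of the failure probabilities
#' (probability scale), one panel per quantity, one line per condition.
#'
#' @param object A `beests_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beests_comparison <- function(object, ...) {
  d <- object$draws |>
    dplyr::mutate(
      value = ifelse(.data$parameter %in% c("ssrt", "go_rt"),
                     .data$value * 1000, .data$value),
      parameter = factor(.data$parameter,
                         levels = c("ssrt", "go_rt", "p_tf", "p_gf"),
                         labels = c("Mean SSRT (ms)", "Mean go RT (ms)",
                                    "P(TF)", "P(GF)")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  colour = .data$condition)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "Posterior density",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}
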