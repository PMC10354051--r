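#' @export
print.beests_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Hierarchical trigger-failure race model fit (condition: %s)\n",
    x$condition))
  cat(sprintf("  %d subjects, %d trials; %d chains x %d iterations (%d burn-in)\n",
              length(x$subjects), x$n_trials, s$chains, s$iter, s$burn))
  r <- rhat(x)
  cat(sprintf("  max univariate R-hat %.3f, multivariate %.3f (%s)\n",
              max(r$rhat), attr(r, "multivariate"),
              if (isTRUE(attr(r, "converged"))) "converged"
              else "NOT converged"))
  cat("\nPopulation-level posterior (mean [95% CI]):\n")
  s95 <- summarise_posterior(x)
  s95 <- s95[grepl("_loc$", s95$parameter), ]
  for (i in seq_len(nrow(s95))) {
    cat(sprintf("  %-14s %6.3f [%6.3f, %6.3f]\n", s95$parameter[i],
                s95$mean[i], s95$lower[i], s95$upper[i]))
  }
  invisible(x)
}

#' Tidy posterior summary of a fitted race model
#'
#' One row per parameter with posterior mean and 95% credible interval
#' (see [summarise_posterior()]).
#'
#' @param x A `beests_fit`.
#' @param ... Passed to [summarise_posterior()].
#' @return A tibble: `parameter`, `mean`, `lower`, `upper`.
#' @export
tidy.beests_fit <- function(x, ...) {
  summarise_posterior(x, ...)
}

#' One-row fit summary
#'
#' @param x A `beests_fit`.
#' @param ... Unused.
#' @return A one-row tibble: subjects, trials, sampler settings, mean
#'   acceptance rate, maximum univariate R-hat, multivariate R-hat and the
#'   convergence verdict.
#' @export
glance.beests_fit <- function(x, ...) {
  r <- rhat(x)
  tibble::tibble(
    condition = x$condition,
    n_subjects = length(x$subjects),
    n_trials = x$n_trials,
    chains = x$settings$chains,
    iter = x$settings$iter,
    burn = x$settings$burn,
    mean_acceptance = mean(x$acceptance),
    max_rhat = max(r$rhat),
    multivariate_rhat = as.numeric(attr(r, "multivariate")),
    converged = isTRUE(attr(r, "converged")))
}

#' Trace and density plot of population-level draws
#'
#' @param object A `beests_fit`.
#' @param parameters Parameters to show; defaults to the population
#'   locations.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beests_fit <- function(object, parameters = NULL, ...) {
  td <- tidy_draws(object)
  if (is.null(parameters)) {
    parameters <- grep("_loc$", names(td), value = TRUE)
  }
  long <- tidyr::pivot_longer(td[, c("chain", "iteration", parameters)],
                              cols = dplyr::all_of(parameters),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration,
                                     y = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Iteration (post burn-in)", y = NULL,
                  colour = "Chain") +
    ggplot2::theme_minimal()
}
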