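#' Posterior predictive check
#'
#' For a random subset of posterior draws, re-simulates every subject's
#' session at the drawn participant-level parameters under the observed
#' SSD sequences (the staircase is not re-run: predictive data are
#' generated at the delays the subject actually experienced), and compares
#' observed to predicted summary statistics: go-RT deciles,
#' signal-respond-RT deciles, and the inhibition rate per SSD bin.
#'
#' @param fit A `beests_fit`.
#' @param trials The observed trial table the model was fitted to.
#' @param n_draws Number of posterior draws to simulate (0 gives an empty
#'   summary).
#' @param seed Integer seed.
#' @param design A [task_design()]; only the response deadline is used.
#' @param n_ssd_bins Number of SSD bins for the inhibition-rate check.
#'
#' @return An object of class `beests_ppc`: a list with `summary`
#'   (tibble: `statistic`, `level`, `observed`, `lower`, `median`,
#'   `upper`, `covered`) and `n_draws`.
#' @export
posterior_predictive <- function(fit, trials, n_draws = 100, seed = 1,
                                 design = task_design(), n_ssd_bins = 4) {
  stopifnot(inherits(fit, "beests_fit"), n_draws >= 0)
  trials <- reduce_for_fit(trials)
  obs_ssd <- trials$ssd[trials$trial_type == "stop"]
  breaks <- unique(stats::quantile(obs_ssd, probs = seq(0, 1,
                                                        length.out = n_ssd_bins + 1)))
  if (length(breaks) < 2) breaks <- range(obs_ssd) + c(-1e-9, 1e-9)
  obs <- pp_stats(trials, breaks)
  if (n_draws == 0) {
    return(structure(list(summary = obs[0, ], n_draws = 0L),
                     class = "beests_ppc"))
  }

  td <- tidy_draws(fit)
  withr::local_seed(derive_seed(seed, 77L))
  idx <- sample.int(nrow(td), n_draws, replace = nrow(td) < n_draws)
  by_subj <- split(trials, trials$subject)

  sims <- purrr::map(seq_len(n_draws), function(d) {
    row <- td[idx[d], ]
    sim <- purrr::imap_dfr(by_subj, function(tr, subj) {
      th <- vapply(race_param_names(), function(p) {
        row[[paste0(p, "[", subj, "]")]]
      }, numeric(1))
      simulate_fixed_ssd(tr, theta_to_race_params(th), design,
                         seed = derive_seed(seed, 100L + d,
                                            match(subj, names(by_subj))),
                         subject = subj)
    })
    pp_stats(sim, breaks)
  })
  pred <- dplyr::bind_rows(sims) |>
    dplyr::group_by(.data$statistic, .data$level) |>
    dplyr::summarise(
      lower = stats::quantile(.data$value, 0.025, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      upper = stats::quantile(.data$value, 0.975, na.rm = TRUE),
      .groups = "drop")
  summary <- obs |>
    dplyr::rename(observed = "value") |>
    dplyr::left_join(pred, by = c("statistic", "level")) |>
    dplyr::mutate(covered = .data$observed >= .data$lower &
                    .data$observed <= .data$upper)
  structure(list(summary = summary, n_draws = as.integer(n_draws)),
            class = "beests_ppc")
}

# simulate one subject's trials at fixed, observed SSDs
simulate_fixed_ssd <- function(trials, r, design, seed, subject = "s01") {
  withr::local_seed(seed)
  n <- nrow(trials)
  is_stop <- trials$trial_type == "stop"
  t_go <- rexgauss(n, r$go)
  t_stop <- rexgauss(n, r$stop)
  gf <- stats::runif(n) < r$p_gf
  tf <- stats::runif(n) < r$p_tf
  response <- logical(n)
  rt <- rep(NA_real_, n)
  ssd <- trials$ssd
  for (i in seq_len(n)) {
    if (gf[i]) next
    beats_stop <- !is_stop[i] || tf[i] || (t_go[i] < ssd[i] + t_stop[i])
    if (beats_stop && t_go[i] <= design$response_deadline) {
      response[i] <- TRUE
      rt[i] <- t_go[i]
    }
  }
  tibble::tibble(subject = subject, trial_type = trials$trial_type,
                 ssd = ssd, response = response, rt = rt,
                 choice_correct = ifelse(response & !is_stop, TRUE, NA))
}

# observed/predicted summary statistics of one trial table
pp_stats <- function(trials, ssd_breaks) {
  probs <- seq(0.1, 0.9, by = 0.1)
  go_rt <- trials$rt[trials$trial_type == "go" & trials$response]
  sr_rt <- trials$rt[trials$trial_type == "stop" & trials$response]
  st <- trials[trials$trial_type == "stop", , drop = FALSE]
  dec <- function(x) {
    if (length(x) < 2) rep(NA_real_, length(probs))
    else stats::quantile(x, probs, names = FALSE)
  }
  bins <- cut(st$ssd, breaks = ssd_breaks, include.lowest = TRUE)
  inh <- tapply(!st$response, bins, mean)
  dplyr::bind_rows(
    tibble::tibble(statistic = "go_rt_decile",
                   level = as.character(probs), value = dec(go_rt)),
    tibble::tibble(statistic = "sr_rt_decile",
                   level = as.character(probs), value = dec(sr_rt)),
    tibble::tibble(statistic = "inhibition_rate",
                   level = names(inh), value = as.numeric(inh)))
}

#' @export
print.beests_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d draws):\n", x$n_draws))
  if (nrow(x$summary)) {
    cov <- mean(x$summary$covered, na.rm = TRUE)
    cat(sprintf("  %.0f%% of observed statistics inside 95%% predictive intervals\n",
                100 * cov))
  }
  invisible(x)
}

#' Observed-vs-predicted plot for a posterior predictive check
#'
#' @param object A `beests_ppc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beests_ppc <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$level)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$median,
                                          ymin = .data$lower,
                                          ymax = .data$upper),
                             colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "red", shape = 4, size = 2) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = "Value",
                  subtitle = "red x = observed; bars = 95% predictive interval") +
    ggplot2::theme_minimal()
}
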