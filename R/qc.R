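#' Race-assumption check
#'
#' The horse-race model implies that signal-respond RTs (failed stops) are
#' a fast-censored sample of the go-RT distribution, so SSRT can only be
#' estimated reliably when the mean signal-respond RT is strictly faster
#' than the mean correct go RT. This check computes both means and the
#' verdict for one subject in one condition.
#'
#' @param trials Trial table for one subject x condition, seconds.
#'
#' @return A one-row tibble: `mean_signal_respond_rt`, `mean_go_rt`,
#'   `race_assumption_ok`.
#' @export
check_race_assumption <- function(trials) {
  sr <- trials$rt[trials$trial_type == "stop" & trials$response]
  go_ok <- trials$trial_type == "go" & trials$response &
    !isFALSE_vec(trials$choice_correct)
  go <- trials$rt[go_ok]
  if (length(sr) < 1 || length(go) < 1) {
    rlang::abort("need at least one signal-respond RT and one correct go RT")
  }
  m_sr <- mean(sr)
  m_go <- mean(go)
  tibble::tibble(mean_signal_respond_rt = m_sr, mean_go_rt = m_go,
                 race_assumption_ok = m_sr < m_go)
}

isFALSE_vec <- function(x) !is.na(x) & !x

#' Responding-rate bounds on stop trials
#'
#' The staircase targets 50% responding on stop trials; estimates become
#' unreliable when the realised p(respond|signal) drifts far from the
#' target. The screen requires `0.25 <= p <= 0.75`.
#'
#' @inheritParams check_race_assumption
#' @return A one-row tibble: `p_respond_signal`, `p_respond_in_bounds`.
#' @export
check_p_respond_bounds <- function(trials) {
  st <- trials[trials$trial_type == "stop", , drop = FALSE]
  if (nrow(st) < 1) rlang::abort("no stop trials")
  p <- mean(st$response)
  tibble::tibble(p_respond_signal = p,
                 p_respond_in_bounds = p >= 0.25 & p <= 0.75)
}

#' Tukey outlier fences
#'
#' Lower and upper fences `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`, with
#' quartiles by linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values Numeric vector, length >= 4.
#' @return Named numeric `c(lower, upper)`.
#' @export
tukey_fences <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) rlang::abort("need at least 4 values for fences")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Remove anticipatory responses
#'
#' Drops responded trials faster than the anticipation threshold
#' (default 0.2 s); such responses are initiated before the stimulus can
#' have been processed. Idempotent.
#'
#' @param trials Trial table, seconds.
#' @param threshold Seconds; responses strictly faster are removed.
#' @return A list: `trials` (filtered table), `n_removed`.
#' @export
remove_anticipatory <- function(trials, threshold = 0.2) {
  drop <- trials$response & !is.na(trials$rt) & trials$rt < threshold
  list(trials = trials[!drop, , drop = FALSE], n_removed = sum(drop))
}

# advisory screen for strategic (near-uniform) go-RT distributions:
# KS distance of the go-RT sample to a uniform on its own range
uniformity_ks_distance <- function(rt) {
  rt <- sort(rt[!is.na(rt)])
  n <- length(rt)
  if (n < 10 || diff(range(rt)) <= 0) return(NA_real_)
  u <- (rt - rt[1]) / (rt[n] - rt[1])
  max(abs(u - (seq_len(n) - 1) / n), abs(u - seq_len(n) / n))
}

#' Cohort data-reduction screen
#'
#' Applies the full data-reduction screen to a cohort trial table:
#' anticipatory responses (< 0.2 s) are removed; per subject x condition
#' the race assumption and the responding-rate bounds are checked; go
#' accuracy outliers are flagged cohort-wide by the Tukey criterion; and
#' subjects must have `required_sessions` complete datasets. A subject is
#' included only if every check passes in every condition. Near-uniform
#' go-RT distributions (a strategic-responding signature) raise an
#' advisory flag and a warning but never auto-exclude.
#'
#' @param trials Cohort trial table, seconds.
#' @param required_sessions Number of complete datasets a subject needs.
#' @param ks_uniform_threshold Advisory threshold on the KS distance of
#'   the go-RT sample to a uniform distribution on its range.
#'
#' @return A tibble with one row per subject x condition: RT means, check
#'   verdicts, accuracy, counts, `complete_sessions` and the
#'   subject-level `include` flag.
#' @export
qc_cohort <- function(trials, required_sessions = 3,
                      ks_uniform_threshold = 0.09) {
  cleaned <- remove_anticipatory(trials)
  tr <- cleaned$trials
  removed <- trials[trials$response & !is.na(trials$rt) & trials$rt < 0.2, ,
                    drop = FALSE]
  rem_tab <- dplyr::count(removed, .data$subject, .data$condition,
                          name = "n_anticipatory_removed")

  per_cell <- tr |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      race <- tryCatch(check_race_assumption(d), error = function(e) {
        tibble::tibble(mean_signal_respond_rt = NA_real_,
                       mean_go_rt = NA_real_, race_assumption_ok = FALSE)
      })
      pr <- tryCatch(check_p_respond_bounds(d), error = function(e) {
        tibble::tibble(p_respond_signal = NA_real_,
                       p_respond_in_bounds = FALSE)
      })
      go <- d[d$trial_type == "go" & d$response, , drop = FALSE]
      acc <- if (nrow(go)) mean(go$choice_correct, na.rm = TRUE) else NA_real_
      dplyr::bind_cols(race, pr, tibble::tibble(
        go_accuracy = acc,
        ks_uniform_distance = uniformity_ks_distance(go$rt)))
    }) |>
    dplyr::ungroup()

  fences <- tukey_fences(per_cell$go_accuracy)
  sessions <- tr |>
    dplyr::distinct(.data$subject, .data$condition) |>
    dplyr::count(.data$subject, name = "complete_sessions")

  out <- per_cell |>
    dplyr::mutate(go_accuracy_outlier =
                    .data$go_accuracy < fences[["lower"]] |
                    .data$go_accuracy > fences[["upper"]],
                  strategic_flag =
                    !is.na(.data$ks_uniform_distance) &
                    .data$ks_uniform_distance < ks_uniform_threshold) |>
    dplyr::left_join(rem_tab, by = c("subject", "condition")) |>
    dplyr::mutate(n_anticipatory_removed =
                    dplyr::coalesce(.data$n_anticipatory_removed, 0L)) |>
    dplyr::left_join(sessions, by = "subject") |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(include = all(.data$race_assumption_ok) &&
                    all(.data$p_respond_in_bounds) &&
                    !any(.data$go_accuracy_outlier) &&
                    .data$complete_sessions[1] == required_sessions) |>
    dplyr::ungroup()

  if (any(out$strategic_flag)) {
    flagged <- unique(out$subject[out$strategic_flag])
    rlang::warn(paste0(
      "near-uniform go-RT distribution (possible strategic responding), ",
      "review: ", paste(flagged, collapse = ", ")))
  }
  out
}
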