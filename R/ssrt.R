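#' Integration-method SSRT with replacement of omissions
#'
#' Nonparametric estimate of the stop-signal reaction time for one subject
#' in one condition. The go-RT distribution is built from *all* go trials
#' (choice errors included), with each omission replaced by the maximum
#' observed go RT; the SSRT is the `ceil(p * N_go)`-th smallest go RT
#' minus the mean SSD over all stop trials, where
#' `p = p(respond|signal)`.
#'
#' @param trials Trial table for one subject x condition, seconds.
#'
#' @return A one-row tibble: `subject`, `condition`, `ssrt`, `mean_ssd`,
#'   `p_respond_signal`, `n_go`, `n_omissions_replaced`.
#' @examples
#' des <- task_design(n_trials = 450, n_blocks = 9)
#' r <- race_params(go = c(0.87, 0.09, 0.10), stop = c(0.42, 0.04, 0.04))
#' estimate_ssrt(simulate_session(des, r, seed = 1))
#' @export
estimate_ssrt <- function(trials) {
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  st <- trials[trials$trial_type == "stop", , drop = FALSE]
  if (nrow(go) < 1 || nrow(st) < 1) {
    rlang::abort("need at least one go trial and one stop trial")
  }
  go_rt <- go$rt[go$response]
  n_omit <- sum(!go$response)
  if (length(go_rt) < 1) rlang::abort("no responded go trials")
  dist <- sort(c(go_rt, rep(max(go_rt), n_omit)))
  n_go <- length(dist)

  p <- mean(st$response)
  if (p <= 0 || p >= 1) {
    rlang::abort(sprintf(
      "SSRT not estimable: p(respond|signal) = %g (needs 0 < p < 1)", p))
  }
  nth <- min(max(ceiling(p * n_go), 1L), n_go)
  mean_ssd <- mean(st$ssd)
  tibble::tibble(
    subject = if ("subject" %in% names(trials)) trials$subject[1] else NA_character_,
    condition = if ("condition" %in% names(trials)) trials$condition[1] else NA_character_,
    ssrt = dist[nth] - mean_ssd,
    mean_ssd = mean_ssd,
    p_respond_signal = p,
    n_go = n_go,
    n_omissions_replaced = n_omit
  )
}

#' Cohort SSRT and descriptive summary table
#'
#' Applies [estimate_ssrt()] per subject x condition and summarises the
#' standard descriptive measures per condition: SSRT, mean SSD, correct
#' go RT, p(respond|signal) and go accuracy (mean and SD across subjects;
#' SD uses the n-1 denominator and is reported as `NA` for a single
#' subject).
#'
#' @param trials Cohort trial table, seconds (QC already applied).
#'
#' @return A list of two tibbles: `by_subject` (one row per subject x
#'   condition) and `by_condition` (one row per condition with `_mean` and
#'   `_sd` columns).
#' @export
cohort_ssrt_table <- function(trials) {
  by_subject <- trials |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      res <- estimate_ssrt(d)
      go <- d[d$trial_type == "go" & d$response, , drop = FALSE]
      correct <- go[!isFALSE_vec(go$choice_correct), , drop = FALSE]
      res$go_rt <- mean(correct$rt)
      res$go_accuracy <- if (nrow(go)) mean(go$choice_correct, na.rm = TRUE)
                         else NA_real_
      res[, setdiff(names(res), c("subject", "condition"))]
    }) |>
    dplyr::ungroup()

  sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  by_condition <- by_subject |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(
      c("ssrt", "mean_ssd", "go_rt", "p_respond_signal", "go_accuracy"),
      list(mean = mean, sd = sd_or_na)), n_subjects = dplyr::n(),
      .groups = "drop")
  list(by_subject = by_subject, by_condition = by_condition)
}
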