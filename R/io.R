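#' Read a trial table
#'
#' Reads a delimited (CSV) trial table and validates it into the package's
#' canonical form: one row per trial with columns `subject`, `condition`,
#' `block`, `trial`, `trial_type` (`"go"`/`"stop"`), `ssd`, `response`,
#' `rt`, `choice_correct` (empty fields for absent values). Extra columns
#' (e.g. `session`, `iti`) are kept. Times are returned in seconds;
#' files recorded in milliseconds are converted with `units = "ms"`.
#'
#' Malformed rows — an SSD on a go trial, a missing SSD on a stop trial,
#' an RT without a response (or vice versa), negative times — are
#' reported with their line numbers.
#'
#' @param path File path.
#' @param units `"s"` (default) or `"ms"`.
#' @return A validated tibble in seconds.
#' @export
read_trials <- function(path, units = c("s", "ms")) {
  units <- match.arg(units)
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject", "condition", "block", "trial", "trial_type",
                "ssd", "response", "rt", "choice_correct")
  missing_cols <- setdiff(required, names(tr))
  if (length(missing_cols)) {
    rlang::abort(paste0("missing required columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  tr$subject <- as.character(tr$subject)
  tr$condition <- as.character(tr$condition)
  tr$trial_type <- as.character(tr$trial_type)
  tr$response <- as.logical(tr$response)
  tr$choice_correct <- as.logical(tr$choice_correct)
  tr$ssd <- as.numeric(tr$ssd)
  tr$rt <- as.numeric(tr$rt)
  if (units == "ms") {
    tr$ssd <- tr$ssd / 1000
    tr$rt <- tr$rt / 1000
    if ("iti" %in% names(tr)) tr$iti <- tr$iti / 1000
  }
  validate_trials(tr)
  tibble::as_tibble(tr)
}

validate_trials <- function(tr) {
  line <- seq_len(nrow(tr)) + 1L  # header is line 1
  bad <- list(
    "unknown trial_type" = !tr$trial_type %in% c("go", "stop"),
    "ssd present on a go trial" = tr$trial_type == "go" & !is.na(tr$ssd),
    "ssd missing on a stop trial" = tr$trial_type == "stop" & is.na(tr$ssd),
    "rt present without a response" = !is.na(tr$rt) &
      (is.na(tr$response) | !tr$response),
    "response without an rt" = !is.na(tr$response) & tr$response &
      is.na(tr$rt),
    "negative rt" = !is.na(tr$rt) & tr$rt < 0,
    "negative ssd" = !is.na(tr$ssd) & tr$ssd < 0
  )
  msgs <- purrr::imap_chr(bad, function(flag, what) {
    if (!any(flag)) return(NA_character_)
    lines <- line[flag]
    shown <- paste(utils::head(lines, 5), collapse = ", ")
    if (length(lines) > 5) shown <- paste0(shown, ", ...")
    sprintf("%s (line %s)", what, shown)
  })
  msgs <- msgs[!is.na(msgs)]
  if (length(msgs)) {
    rlang::abort(paste0("invalid trial table:\n  ",
                        paste(msgs, collapse = "\n  ")))
  }
  invisible(tr)
}

#' Write a trial table
#'
#' Inverse of [read_trials()]: writes a CSV (comma, UTF-8, header) with
#' empty fields for absent values. `units = "ms"` writes times in
#' milliseconds.
#'
#' @param trials A trial table in seconds.
#' @param path Output path.
#' @inheritParams read_trials
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, units = c("s", "ms")) {
  units <- match.arg(units)
  if (units == "ms") {
    trials$ssd <- trials$ssd * 1000
    trials$rt <- trials$rt * 1000
    if ("iti" %in% names(trials)) trials$iti <- trials$iti * 1000
  }
  readr::write_csv(trials, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' Parses and validates a YAML pipeline configuration with blocks
#' `design` ([task_design()] arguments), `cohort` (`n_subjects`,
#' `conditions`, optional per-condition `population` location/scale
#' overrides), `priors` ([prior_spec()] arguments), `sampler` (`chains`,
#' `iter`, `burn`, `thin`), `io` (`out_dir`, optional `trials_file`),
#' `units` (`"s"`/`"ms"`) and `seed`. Unknown top-level or block keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("design", "cohort", "priors", "sampler", "io", "units", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config keys: ",
                        paste(unknown, collapse = ", ")))
  }
  check_block <- function(block, allowed) {
    extra <- setdiff(names(cfg[[block]]), allowed)
    if (length(extra)) {
      rlang::abort(sprintf("unknown keys in `%s`: %s", block,
                           paste(extra, collapse = ", ")))
    }
  }
  check_block("design", names(formals(task_design)))
  check_block("cohort", c("n_subjects", "conditions", "population"))
  check_block("priors", names(formals(prior_spec)))
  check_block("sampler", c("chains", "iter", "burn", "thin"))
  check_block("io", c("out_dir", "trials_file"))
  cfg$units <- match.arg(cfg$units %||% "s", c("s", "ms"))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_population <- function(pop_cfg) {
  defaults <- population_defaults()
  if (is.null(pop_cfg)) return(defaults)
  loc <- defaults$location
  sc <- defaults$scale
  if (!is.null(pop_cfg$location)) loc[names(pop_cfg$location)] <-
      unlist(pop_cfg$location)
  if (!is.null(pop_cfg$scale)) sc[names(pop_cfg$scale)] <-
      unlist(pop_cfg$scale)
  population_params(loc, sc)
}

#' Run the full analysis pipeline
#'
#' Drives the end-to-end analysis deterministically under the master
#' seed: simulate (or read) trials, apply the data-reduction screen,
#' tabulate integration-method SSRTs, fit the hierarchical race model per
#' condition, summarise and compare posteriors, and write every artifact
#' (CSV tables, posterior draws, JSON metadata with seeds and R-hat
#' values, figures) to the output directory. A stage failure aborts with
#' the failing stage named; artifacts written before the failure are
#' retained.
#'
#' @param config A `pipeline_config` (or the path to one).
#' @param out_dir Output directory; overrides `config$io$out_dir`.
#' @param progress Print stage progress?
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, progress = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$io$out_dir %||% "stopsignal-artifacts"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (progress) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)))
    })
  }
  log <- list(package_version = as.character(utils::packageVersion("stopsignal")),
              r_version = R.version.string, seed = config$seed,
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  design <- do.call(task_design, config$design %||% list())
  conds <- as.character(config$cohort$conditions %||% "cond1")

  trials <- stage("simulate", {
    if (!is.null(config$io$trials_file)) {
      say("reading trials from %s", config$io$trials_file)
      read_trials(config$io$trials_file, units = config$units)
    } else {
      say("simulating cohort (%d subjects x %d conditions)",
          config$cohort$n_subjects, length(conds))
      cohort <- simulate_cohort(
        n_subjects = config$cohort$n_subjects %||% 8L,
        populations = config_population(config$cohort$population),
        design = design, seed = config$seed, conditions = conds)
      readr::write_csv(cohort$params,
                       file.path(out_dir, "true_params.csv"), na = "")
      write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
      cohort$trials
    }
  })

  qc <- stage("qc", qc_cohort(trials,
                              required_sessions = length(conds)))
  readr::write_csv(qc, file.path(out_dir, "qc_report.csv"), na = "")
  kept <- unique(qc$subject[qc$include])
  say("qc: %d/%d subjects retained", length(kept),
      length(unique(trials$subject)))
  trials_kept <- trials[trials$subject %in% kept, , drop = FALSE]
  trials_kept <- remove_anticipatory(trials_kept)$trials

  ssrt_tab <- stage("ssrt", cohort_ssrt_table(trials_kept))
  readr::write_csv(ssrt_tab$by_subject,
                   file.path(out_dir, "ssrt_by_subject.csv"), na = "")
  readr::write_csv(ssrt_tab$by_condition,
                   file.path(out_dir, "descriptives_by_condition.csv"),
                   na = "")

  sampler <- config$sampler %||% list()
  fits <- stage("fit", {
    purrr::map(stats::setNames(conds, conds), function(cn) {
      say("fitting condition %s", cn)
      fit_beests(trials_kept[trials_kept$condition == cn, , drop = FALSE],
                 priors = do.call(prior_spec, config$priors %||% list()),
                 chains = sampler$chains %||% 3L,
                 iter = sampler$iter %||% 5000L,
                 burn = sampler$burn %||% 2500L,
                 thin = sampler$thin %||% 1L,
                 seed = derive_seed(config$seed, match(cn, conds), 500L))
    })
  })

  rhats <- purrr::map(fits, rhat)
  log$rhat <- purrr::imap(rhats, function(r, cn) {
    list(max_univariate = max(r$rhat),
         multivariate = as.numeric(attr(r, "multivariate")),
         converged = isTRUE(attr(r, "converged")),
         failures = r$parameter[r$rhat >= 1.1])
  })
  all_conv <- all(vapply(rhats, function(r) isTRUE(attr(r, "converged")),
                         logical(1)))
  say("convergence rule (all R-hat < 1.1): %s",
      if (all_conv) "satisfied" else "NOT satisfied")

  for (cn in conds) {
    readr::write_csv(tidy_draws(fits[[cn]]),
                     file.path(out_dir, sprintf("draws_%s.csv", cn)))
    readr::write_csv(summarise_posterior(fits[[cn]]),
                     file.path(out_dir, sprintf("posterior_summary_%s.csv",
                                                cn)))
  }

  if (length(conds) >= 2) {
    cmp <- stage("compare", compare_conditions(fits))
    readr::write_csv(cmp$bp, file.path(out_dir, "bayesian_p_values.csv"))
    ggplot2::ggsave(file.path(out_dir, "posterior_overlap.pdf"),
                    ggplot2::autoplot(cmp), width = 8, height = 6)
  }

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, file.path(out_dir, "pipeline_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
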