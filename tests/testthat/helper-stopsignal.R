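# shared fixtures: all data are generated in code, no files

# canonical healthy-adult parameter set (mean go RT 0.97 s, mean SSRT 0.46 s)
ref_race <- function(p_tf = 0, p_gf = 0) {
  race_params(go = c(0.87, 0.09, 0.10), stop = c(0.42, 0.04, 0.04),
              p_tf = p_tf, p_gf = p_gf)
}

# minimal hand-built trial table
make_trials <- function(go_rt = numeric(), go_omit = 0,
                        sr_rt = numeric(), sr_ssd = numeric(),
                        inhib_ssd = numeric(), subject = "s01",
                        condition = "c1", go_correct = NULL) {
  n_go <- length(go_rt) + go_omit
  n_stop <- length(sr_rt) + length(inhib_ssd)
  if (is.null(go_correct)) go_correct <- rep(TRUE, length(go_rt))
  tibble::tibble(
    subject = subject, condition = condition, block = 1L,
    trial = seq_len(n_go + n_stop),
    trial_type = c(rep("go", n_go), rep("stop", n_stop)),
    ssd = c(rep(NA_real_, n_go), sr_ssd, inhib_ssd),
    response = c(rep(TRUE, length(go_rt)), rep(FALSE, go_omit),
                 rep(TRUE, length(sr_rt)), rep(FALSE, length(inhib_ssd))),
    rt = c(go_rt, rep(NA_real_, go_omit), sr_rt,
           rep(NA_real_, length(inhib_ssd))),
    choice_correct = c(go_correct, rep(NA, go_omit),
                       rep(NA, n_stop))
  )
}

# a fake fitted object with known population draws, for summary/comparison
# tests that should not depend on the sampler
fake_fit <- function(draws_by_param, chains = 2, condition = "c1") {
  n <- length(draws_by_param[[1]]) / chains
  arr <- array(NA_real_, dim = c(n, chains, length(draws_by_param)),
               dimnames = list(iteration = NULL,
                               chain = paste0("chain", seq_len(chains)),
                               parameter = names(draws_by_param)))
  for (p in seq_along(draws_by_param)) {
    arr[, , p] <- matrix(draws_by_param[[p]], n, chains)
  }
  structure(list(draws = arr, subjects = "s01", condition = condition,
                 settings = list(chains = chains, iter = 2 * n, burn = n,
                                 thin = 1, seed = 0),
                 acceptance = matrix(0.3, chains, 1), n_trials = 0L,
                 single_subject = TRUE),
            class = "beests_fit")
}
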