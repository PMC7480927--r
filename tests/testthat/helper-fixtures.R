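# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A short default-parameter recording used by several feature tests.
fixture_recording <- function() {
  cached("rec26", simulate_preterm_eeg(26, duration = 600, fs = 128, seed = 1))
}

# Small cohort with extracted epoch features for the FBA unit tests.
fixture_mini_features <- function() {
  cached("mini_feats", {
    cohort <- simulate_cohort(12, recordings_per_infant = 2, duration = 180,
                              fs = 64, seed = 3)
    extract_cohort_features(cohort, qeeg_config(epoch_s = 90,
                                                min_duration_s = 90))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Long-format panel table from an n x k ratings matrix.
panel_from_matrix <- function(m) {
  tibble::tibble(recording_id = rep(rownames(m) %||%
                                      sprintf("r%03d", seq_len(nrow(m))),
                                    ncol(m)),
                 rater_id = rep(sprintf("R%d", seq_len(ncol(m))),
                                each = nrow(m)),
                 estimate_weeks = as.vector(m))
}

# Per-row (single-epoch) predictions through the public recording API.
predict_epochs_test <- function(model, feats) {
  vapply(seq_len(nrow(feats)), function(i) {
    one <- feats[i, ]
    one$recording_id <- "single"
    predict_fba(model, one)$fba_weeks
  }, 0)
}

# Truth table at the study's agreement-cohort scale (179 recordings).
fixture_truth_179 <- function() {
  cached("truth179", {
    set.seed(179)
    tibble::tibble(recording_id = sprintf("r%03d", 1:179),
                   infant_id = sprintf("i%02d", rep(1:62, length.out = 179)),
                   pma_weeks = runif(179, 25, 38))
  })
}
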