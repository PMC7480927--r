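test_that("estimate tables round-trip through TSV", {
  truth <- fixture_truth_179()[1:10, ]
  tab <- simulate_rater_panel(truth, rater_panel_eeg(), seed = 61)
  path <- tempfile(fileext = ".tsv")
  write_estimates_tsv(tab, path)
  back <- read_estimates_tsv(path)
  expect_equal(back$estimate_weeks, tab$estimate_weeks, tolerance = 1e-9)
  expect_equal(tidy(icc_agreement(back)), tidy(icc_agreement(tab)),
               tolerance = 1e-9)
  expect_error(write_estimates_tsv(tab[, 1:3], tempfile()),
               class = "neofba_input_error")
})

test_that("error decomposition matches hand computation", {
  es <- error_summary(c(31, 31, 36), c(30, 32, 34))
  expect_equal(es$systematic_error, 2 / 3)
  expect_equal(es$random_error, sd(c(1, -1, 2)))
  expect_equal(es$pct_within_1wk, 100 * 2 / 3)
  expect_equal(es$pct_within_2wk, 100)

  perfect <- error_summary(c(26, 30), c(26, 30))
  expect_equal(perfect$systematic_error, 0)
  expect_equal(perfect$random_error, 0)
  expect_equal(perfect$pct_within_1wk, 100)

  offset <- error_summary(c(26, 30, 34) + 0.8, c(26, 30, 34))
  expect_equal(offset$systematic_error, 0.8)
  expect_equal(offset$random_error, 0)
  expect_error(error_summary(1, 1), class = "neofba_input_error")
})

test_that("mean squared error decomposes exactly into bias and variance", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    est <- rnorm(n, 30, 3); tru <- rnorm(n, 30, 3)
    es <- error_summary(est, tru)
    mse <- mean((est - tru)^2)
    expect_equal(mse,
                 es$systematic_error^2 + es$random_error^2 * (n - 1) / n,
                 tolerance = 1e-12)
  }
})

test_that("ensemble averaging cancels bias and shrinks noise as sigma/sqrt(k)", {
  truth <- tibble::tibble(recording_id = sprintf("r%04d", 1:2000),
                          infant_id = sprintf("i%04d", 1:2000),
                          pma_weeks = runif(2000, 25, 38))
  one <- simulate_rater_panel(truth, list(rater_spec("A", 0.5, 1)), seed = 2)
  expect_equal(ensemble_estimate(one)$estimate_weeks,
               dplyr::arrange(one, recording_id)$estimate_weeks)

  pair <- simulate_rater_panel(truth, list(rater_spec("A", 2, 0),
                                           rater_spec("B", -2, 0)), seed = 2)
  ens <- ensemble_estimate(pair)
  expect_equal(error_summary(ens$estimate_weeks, ens$pma_weeks)$systematic_error,
               0, tolerance = 1e-12)

  four <- simulate_rater_panel(truth,
                               purrr::map(1:4, ~ rater_spec(paste0("R", .x),
                                                            0, 2.5)),
                               seed = 3)
  ens4 <- ensemble_estimate(four)
  re <- error_summary(ens4$estimate_weeks, ens4$pma_weeks)$random_error
  expect_lt(abs(re - 1.25) / 1.25, 0.1)
})

test_that("systematic-error tests match their closed forms", {
  same <- compare_systematic_error(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)

  # textbook five-pair case, paired t by hand
  a <- c(0.8, 1.5, -0.2, 2.1, 0.4)
  b <- c(-0.5, 0.3, -1.0, 0.9, -0.2)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  res <- compare_systematic_error(a, b, paired = TRUE)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$cohens_d, mean(d) / sd(d), tolerance = 1e-12)

  w <- compare_systematic_error(a, b, paired = FALSE)
  expect_equal(w$test, "welch_t")
  expect_lt(w$df, 8)  # Satterthwaite df below n1 + n2 - 2
})

test_that("a bias at the study scale is detected with near-certain power", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    a <- rnorm(146, -1.8, 1); b <- rnorm(146, 0, 1)
    hits <- hits + (compare_systematic_error(a, b, TRUE)$p_value < 0.001)
  }
  expect_gte(hits, 50 * 0.99)
})

test_that("Pitman-Morgan equals its variance-ratio formulation", {
  same <- compare_random_error(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(23)
  for (i in 1:20) {
    xy <- rnorm_pair(30, 0.5)
    a <- xy[, 1] * 1.3; b <- xy[, 2]
    res <- compare_random_error(a, b, paired = TRUE)
    expect_equal(res$statistic, pitman_morgan_oracle(a, b), tolerance = 1e-10)
    expect_equal(res$df, 28)
  }
  un <- compare_random_error(rnorm(30), rnorm(40, sd = 2), paired = FALSE)
  expect_equal(un$test, "bartlett")
  expect_lt(un$p_value, 0.05)
})

test_that("Pitman-Morgan and Bartlett agree for uncorrelated pairs", {
  agree <- 0
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(500, sd = sample(c(1, 1.2), 1)); b <- rnorm(500)
    pm <- compare_random_error(a, b, paired = TRUE)$p_value < 0.05
    bt <- compare_random_error(a, b, paired = FALSE)$p_value < 0.05
    agree <- agree + (pm == bt)
  }
  expect_gte(agree, 90)
})

test_that("the ensemble beats every individual rater under independent noise", {
  truth <- tibble::tibble(recording_id = sprintf("r%03d", 1:146),
                          infant_id = sprintf("i%03d", 1:146),
                          pma_weeks = runif(146, 25, 38))
  raters <- purrr::map(1:4, ~ rater_spec(paste0("R", .x), 0, 2.5))
  wins <- 0
  for (s in 1:100) {
    tab <- simulate_rater_panel(truth, raters, seed = 900 + s)
    per <- tab |>
      dplyr::group_by(rater_id) |>
      dplyr::summarise(re = sd(estimate_weeks - pma_weeks))
    ens <- ensemble_estimate(tab)
    ens_re <- sd(ens$estimate_weeks - ens$pma_weeks)
    wins <- wins + (ens_re <= min(per$re))
  }
  expect_gte(wins, 95)
})

test_that("trajectory analysis applies the two-recording inclusion rule", {
  df <- tibble::tibble(
    infant_id = c("a", "a", "b", "b", "d", "d", "c"),
    method = "EEG",
    pma_weeks = c(26, 28, 27, 29, 26, 30, 30),
    estimate_weeks = c(26.5, 27.5, 27, 30, 27, 29.5, 31))
  df <- dplyr::bind_rows(
    df, dplyr::mutate(df, method = "FBA",
                      estimate_weeks = pma_weeks +
                        c(0.1, -0.1, 0.2, -0.2, 0.3, -0.3, 0)))
  tr <- trajectory_analysis(df)
  expect_false("c" %in% tr$per_infant_sd$infant_id)
  expect_equal(sort(unique(tr$per_infant_sd$infant_id)), c("a", "b", "d"))
  expect_error(trajectory_analysis(df[df$method == "EEG", ]),
               class = "neofba_input_error")
})

test_that("identical error tables give a null trajectory ANOVA", {
  base <- tidyr::crossing(infant_id = sprintf("i%02d", 1:10), k = 1:3) |>
    dplyr::mutate(pma_weeks = 28 + k * 2)
  set.seed(25)
  base$estimate_weeks <- base$pma_weeks + rnorm(nrow(base))
  df <- dplyr::bind_rows(dplyr::mutate(base, method = "A"),
                         dplyr::mutate(base, method = "B"))
  tr <- trajectory_analysis(df)
  expect_equal(tr$anova$F, 0, tolerance = 1e-12)
  expect_equal(tr$anova$p_value, 1)
})

test_that("subgroup analysis applies the Bonferroni rule and size contract", {
  expect_equal(bonferroni_groupings(0.02, 3), 0.06)
  expect_equal(bonferroni_groupings(0.5, 3), 1)

  truth <- fixture_truth_179()
  tab <- simulate_rater_panel(truth, rater_panel_aeeg(), seed = 41)
  labels <- tibble::tibble(recording_id = truth$recording_id,
                           abnormal = seq_len(179) <= 49)
  res <- subgroup_analysis(tab, labels, n_boot = 100, seed = 1)
  expect_equal(res$per_group$group, c("normal", "abnormal"))
  expect_equal(res$per_group$n, c(130, 49))
  expect_equal(res$tests$p_adj, pmin(res$tests$p_value * 3, 1))

  empty <- tibble::tibble(recording_id = truth$recording_id, abnormal = FALSE)
  expect_error(subgroup_analysis(tab, empty),
               class = "neofba_groupsize_error")
})

test_that("random labels on a homogeneous panel stay at the nominal level", {
  truth <- fixture_truth_179()[1:80, ]
  tab <- simulate_rater_panel(truth, rater_panel_aeeg(), seed = 43)
  n_rep <- 100
  rej <- c(welch = 0, bartlett = 0)
  for (s in 1:n_rep) {
    set.seed(s)
    labels <- tibble::tibble(recording_id = truth$recording_id,
                             abnormal = sample(c(TRUE, FALSE), 80,
                                               replace = TRUE))
    if (sum(labels$abnormal) < 3 || sum(!labels$abnormal) < 3) next
    res <- subgroup_analysis(tab, labels, n_boot = 50, seed = s)
    rej <- rej + (res$tests$p_adj < 0.05)
  }
  expect_lte(rej[["welch"]] / n_rep, 0.05)
  expect_lte(rej[["bartlett"]] / n_rep, 0.05)
})
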