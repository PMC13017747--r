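test_that("every base learner fits, predicts probabilities, and is seeded", {
  gen <- small_synth(n = 400, seed = 3, missing_rate = 0.1)
  parts <- split_cohort(gen$table, split_spec(seed = 1))
  for (nm in names(default_model_specs())) {
    sp <- model_spec(nm, seed = 7)
    fit <- fit_model(sp, parts$train)
    p <- predict_proba(fit, parts$test)
    expect_length(p, nrow(parts$test))
    expect_true(all(p >= 0 & p <= 1), info = nm)
    # determinism: same spec + seed, identical predictions
    p2 <- predict_proba(fit_model(sp, parts$train), parts$test)
    expect_identical(p, p2, info = nm)
  }
})

test_that("row order at prediction time is irrelevant (name alignment)", {
  gen <- small_synth(n = 300, seed = 5)
  parts <- split_cohort(gen$table, split_spec(seed = 2))
  fit <- fit_model(model_spec("gbm_leafwise", seed = 1), parts$train)
  p <- predict_proba(fit, parts$test)
  perm <- with_test_seed(9, sample.int(nrow(parts$test)))
  df_perm <- as.data.frame(parts$test)[perm, ]
  expect_equal(predict_proba(fit, df_perm), p[perm], tolerance = 1e-12)
  # shuffled columns align by name
  df_cols <- df_perm[, rev(names(df_perm))]
  expect_equal(predict_proba(fit, df_cols), p[perm], tolerance = 1e-12)
  # missing feature column errors by name
  expect_error(predict_proba(fit, df_perm[, -which(names(df_perm) == "ses_01")]),
               "ses_01")
})

test_that("logistic separates a separable toy and constants predict prevalence", {
  n <- 60
  df <- data.frame(id = seq_len(n), death = rep(c(0, 1), each = n / 2),
                   age = rep(c(55, 85), each = n / 2),
                   female = rep(c(0, 1), n / 2),
                   x = rep(c(-2, 2), each = n / 2) + rnorm(n, sd = 0.05))
  tbl <- cohort_table(df)
  fit <- fit_model(model_spec("logistic", seed = 1), tbl,
                   feature_subset = c("x", "female", "age"))
  acc <- mean((predict_proba(fit, tbl) > 0.5) == outcomes(tbl))
  expect_equal(acc, 1.0)
  # constant features: every model output collapses to train prevalence
  df$x <- 1; df$age <- 60; df$female <- 1
  tbl2 <- cohort_table(df)
  fit2 <- fit_model(model_spec("decision_tree", seed = 1), tbl2)
  expect_equal(predict_proba(fit2, tbl2), rep(0.5, n), tolerance = 1e-9)
})

test_that("boosted learners consume missingness natively; others impute from train", {
  gen <- small_synth(n = 500, seed = 8, missing_rate = 0.3)
  parts <- split_cohort(gen$table, split_spec(seed = 3))
  fit <- fit_model(model_spec("gbm_leafwise", seed = 2), parts$train)
  expect_null(fit$prep)
  p <- predict_proba(fit, parts$test)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  # imputation statistics are computed from training rows only
  fit_lr <- fit_model(model_spec("logistic", seed = 2), parts$train)
  Xtr <- feature_matrix(parts$train)
  expect_equal(fit_lr$prep$medians,
               apply(Xtr, 2, median, na.rm = TRUE))
  # and are unchanged by whatever the test rows contain
  fit_lr2 <- fit_model(model_spec("logistic", seed = 2), parts$train)
  expect_identical(fit_lr$prep, fit_lr2$prep)
})

test_that("benchmark model uses exactly age and gender", {
  gen <- small_synth(n = 400, seed = 12)
  parts <- split_cohort(gen$table, split_spec(seed = 1))
  bm <- fit_benchmark(parts$train)
  expect_identical(bm$feature_names, c("age", "female"))
  # age-only-signal cohort: benchmark matches the full model
  spec <- cohort_spec(n = 4000, domain_sizes = c(demography = 2, a = 4),
                      domain_betas = list(demography = numeric(0),
                                          a = rep(0, 4)),
                      age_beta_linear = 1.5, gender_beta = 0,
                      target_prevalence = 0.3, missing_rate = 0, seed = 31)
  gen2 <- generate_cohort(spec)
  parts2 <- split_cohort(gen2$table, split_spec(seed = 1))
  y <- outcomes(parts2$test)
  auc_bm <- roc_auc(y, predict_proba(fit_benchmark(parts2$train), parts2$test))
  full <- fit_model(model_spec("logistic", seed = 1), parts2$train)
  auc_full <- roc_auc(y, predict_proba(full, parts2$test))
  expect_lt(abs(auc_bm - auc_full), 0.02)
  # cohort without the gender column cannot build a benchmark
  df <- as.data.frame(gen$table)
  df$female <- NULL
  expect_error(cohort_table(df), "female")
})

test_that("super learner weights follow out-of-fold log-loss", {
  # meta-learner oracle: grid search over the 2-simplex
  y <- with_test_seed(4, rbinom(400, 1, 0.4))
  p_good <- pmin(pmax(ifelse(y == 1, 0.9, 0.1) +
                                  with_test_seed(5, rnorm(400, 0, 0.05)),
                                0.01), 0.99)
  p_rand <- with_test_seed(6, runif(400))
  Z <- cbind(p_good, p_rand)
  w <- mortdomains:::solve_convex_logloss_weights(y, Z)
  expect_gt(w[1], 0.9)
  grid <- seq(0, 1, by = 0.001)
  ll <- vapply(grid, function(a) {
    p <- pmin(pmax(a * Z[, 1] + (1 - a) * Z[, 2], 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }, numeric(1))
  expect_lt(abs(w[1] - grid[which.min(ll)]), 0.01)

  gen <- small_synth(n = 500, seed = 14)
  # degenerate single-base call puts all weight on that learner
  sl1 <- fit_super_learner(list(model_spec("logistic")), gen$table,
                           k_folds = 3, seed = 2)
  expect_equal(sl1$weights, 1)
  # ensemble log-loss does not exceed the best base out-of-fold log-loss
  sl <- fit_super_learner(list(model_spec("gbm_leafwise"),
                               model_spec("logistic"),
                               model_spec("naive_bayes")),
                          gen$table, k_folds = 3, seed = 2)
  expect_equal(sum(sl$weights), 1, tolerance = 1e-8)
  expect_true(all(sl$weights >= -1e-12))
  p_sl <- predict_proba(sl, gen$table)
  ll_sl <- -mean(outcomes(gen$table) * log(pmax(p_sl, 1e-12)) +
                 (1 - outcomes(gen$table)) * log(pmax(1 - p_sl, 1e-12)))
  expect_lt(ll_sl, min(sl$oof_logloss) + 0.01)
})

test_that("evaluate_suite reports all metrics per model across seeds", {
  gen <- small_synth(n = 500, seed = 20)
  specs <- list(gbm = model_spec("gbm_leafwise"),
                lr = model_spec("logistic"))
  rep <- evaluate_suite(specs, gen$table, split_spec(), seeds = 1:3)
  df <- as.data.frame(rep)
  # 2 models + benchmark, 5 metrics each
  expect_equal(nrow(df), 15L)
  expect_equal(unique(df$n_seeds), 3L)
  per_seed <- attr(rep, "per_seed")
  expect_equal(nrow(per_seed), 45L)
  expect_true(all(df$mean[df$metric %in% c("roc_auc", "pr_auc")] >= 0 &
                  df$mean[df$metric %in% c("roc_auc", "pr_auc")] <= 1))
  # IP equals the mean test prevalence over seeds
  ip <- vapply(1:3, function(s) {
    mean(outcomes(split_cohort(gen$table, split_spec(seed = s))$test))
  }, numeric(1))
  expect_equal(attr(rep, "in_sample_prevalence"), mean(ip), tolerance = 1e-12)
  # planted non-demographic signal: boosted model beats the benchmark
  expect_gt(df$mean[df$model == "gbm" & df$metric == "pr_auc"],
            df$mean[df$model == "benchmark" & df$metric == "pr_auc"])
})
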