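# Independent path-dependent payoff on an extracted tree: condition on
# the features in S (follow x), average the rest by training cover.
# Split comparisons follow the booster's float32 semantics.
as_f32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          size = 4L, n = length(v))
}

payoff_tree <- function(tree, x, S, node = 1L) {
  if (tree$feature[node] < 0) return(tree$value[node])
  f <- tree$feature[node] + 1L  # 1-based feature index
  yes <- tree$yes[node] + 1L; no <- tree$no[node] + 1L
  mis <- tree$missing[node] + 1L
  if (f %in% S) {
    nxt <- if (is.na(x[f])) mis
           else if (as_f32(x[f]) < as_f32(tree$split[node])) yes else no
    payoff_tree(tree, x, S, nxt)
  } else {
    w <- tree$cover[node]
    (tree$cover[yes] / w) * payoff_tree(tree, x, S, yes) +
      (tree$cover[no] / w) * payoff_tree(tree, x, S, no)
  }
}

brute_force_tree_shap <- function(parsed, x, p) {
  subsets <- list(integer(0))
  for (j in seq_len(p)) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, j)))
  }
  v <- function(S) {
    parsed$base_offset +
      sum(vapply(parsed$trees, payoff_tree, numeric(1), x = x, S = S))
  }
  vals <- vapply(subsets, v, numeric(1))
  names(vals) <- vapply(subsets, paste, character(1), collapse = ",")
  vapply(seq_len(p), function(j) {
    tot <- 0
    for (k in seq_along(subsets)) {
      S <- subsets[[k]]
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      key <- paste(sort(c(S, j)), collapse = ",")
      tot <- tot + w * (vals[[key]] - vals[[k]])
    }
    tot
  }, numeric(1))
}

test_that("single-stump attribution equals the margin shift on the split feature", {
  n <- 200
  df <- data.frame(id = seq_len(n),
                   death = rep(c(0, 1), each = n / 2),
                   age = rep(60, n), female = rep(1, n),
                   x = rep(c(-1, 1), each = n / 2))
  tbl <- cohort_table(df)
  fit <- fit_model(model_spec("xgboost", seed = 1,
                              hyperparams = list(nrounds = 1, max_depth = 1,
                                                 eta = 1)),
                   tbl)
  sh <- compute_shap(fit, tbl)
  marg <- predict_margin(fit, tbl)
  expect_equal(sh$attributions[, "x"], marg - sh$base_value,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(sh$attributions[, c("age", "female")] == 0))
})

test_that("tree attributions match brute-force Shapley with path-dependent payoffs", {
  n <- 300
  df <- with_test_seed(8, data.frame(
    id = seq_len(n), death = rbinom(n, 1, 0.5),
    age = runif(n, 50, 100), female = rbinom(n, 1, 0.5)))
  df$death <- with_test_seed(9, rbinom(n, 1, plogis((df$age - 75) / 10 - df$female)))
  if (length(unique(df$death)) < 2) df$death[1:2] <- c(0, 1)
  tbl <- cohort_table(df, feature_cols = c("age", "female"))
  fit <- fit_model(model_spec("xgboost", seed = 3,
                              hyperparams = list(nrounds = 3, max_depth = 3)),
                   tbl)
  sh <- compute_shap(fit, tbl)
  parsed <- mortdomains:::parse_booster_trees(fit)
  X <- feature_matrix(tbl)
  for (i in c(1, 57, 200)) {
    oracle <- brute_force_tree_shap(parsed, X[i, ], p = 2L)
    expect_equal(unname(sh$attributions[i, ]), oracle, tolerance = 1e-10)
  }
})

test_that("tree attributions agree with the booster's own attribution pass", {
  gen <- small_synth(n = 400, seed = 31, missing_rate = 0.1)
  fit <- fit_model(model_spec("gbm_leafwise", seed = 2), gen$table)
  sh <- compute_shap(fit, gen$table)
  X <- feature_matrix(gen$table)
  native <- predict(fit$handle, xgboost::xgb.DMatrix(X, missing = NA),
                    predcontrib = TRUE)
  expect_lt(max(abs(sh$attributions -
                    native[, seq_along(fit$feature_names)])), 1e-4)
  expect_equal(sh$base_value, unname(native[1, ncol(native)]),
               tolerance = 1e-5)
})

test_that("local accuracy holds row-wise for tree and model-agnostic methods", {
  gen <- small_synth(n = 250, seed = 13, missing_rate = 0.1)
  fit <- fit_model(model_spec("gbm_leafwise", seed = 4), gen$table)
  sh <- compute_shap(fit, gen$table)
  expect_lt(local_accuracy_error(sh, predict_margin(fit, gen$table)), 1e-8)

  # exact interventional Shapley on a logistic model (9 features)
  fit_lr <- fit_model(model_spec("logistic", seed = 1), gen$table)
  sub <- as.data.frame(gen$table)[1:25, ]
  sub_tbl <- cohort_table(sub, feature_cols = feature_names(gen$table))
  sh_ex <- compute_shap(fit_lr, sub_tbl, method = "exact",
                        background = sub_tbl)
  expect_lt(local_accuracy_error(sh_ex, predict_margin(fit_lr, sub_tbl)),
            1e-9)
  # sampling fallback satisfies local accuracy by telescoping
  sh_sm <- compute_shap(fit_lr, sub_tbl, method = "sampling",
                        background = sub_tbl, n_permutations = 5)
  expect_lt(local_accuracy_error(sh_sm, predict_margin(fit_lr, sub_tbl)),
            1e-9)
})

test_that("duplicated features receive symmetric attributions (exact method)", {
  n <- 120
  df <- with_test_seed(3, {
    x <- rnorm(n)
    data.frame(id = seq_len(n), death = rbinom(n, 1, plogis(x)),
               age = runif(n, 50, 100), female = rbinom(n, 1, 0.5),
               dup1 = x, dup2 = x)
  })
  if (length(unique(df$death)) < 2) df$death[1:2] <- c(0, 1)
  tbl <- cohort_table(df, feature_cols = c("age", "female", "dup1", "dup2"))
  # naive Bayes factorizes over features, so exact duplicates enter the
  # model identically and must receive identical attributions
  fit <- fit_model(model_spec("naive_bayes", seed = 1), tbl)
  sh <- compute_shap(fit, tbl, method = "exact", background = tbl)
  ms <- colMeans(abs(sh$attributions))
  expect_lt(abs(ms[["dup1"]] - ms[["dup2"]]), 1e-6)
})

test_that("mean_abs_shap ranks with alphabetical tie-breaks and thresholds", {
  mat <- cbind(a = c(-1, 1), zero = c(0, 0), b = c(0.5, -0.5),
               tie = c(1, -1))
  sh <- structure(list(attributions = mat, base_value = 0,
                       feature_names = colnames(mat), scale = "log_odds"),
                  class = "shap_matrix")
  summ <- mean_abs_shap(sh)
  expect_equal(summ$feature, c("a", "tie", "b", "zero"))
  expect_equal(summ$mean_abs_shap, c(1, 1, 0.5, 0))
  expect_equal(summ$rank, 1:4)
  expect_equal(top_factors(summ, threshold = 0.1), c("a", "tie", "b"))
  expect_equal(top_factors(summ, threshold = 2), character(0))
  expect_equal(top_factors(summ, threshold = 0), c("a", "tie", "b"))
})

test_that("age stratification is consistent, flags thin bins, rejects overlap", {
  gen <- small_synth(n = 300, seed = 6)
  fit <- fit_model(model_spec("gbm_leafwise", seed = 2), gen$table)
  sh <- compute_shap(fit, gen$table)
  # single bin covering all ages equals the overall summary
  one <- age_stratified_shap(sh, gen$table, breaks = c(50, 110))
  overall <- mean_abs_shap(sh)
  m1 <- setNames(one$mean_abs_shap, one$feature)
  expect_equal(m1[overall$feature],
               setNames(overall$mean_abs_shap, overall$feature),
               tolerance = 1e-12)
  expect_false(any(one$unstable))
  # an empty bin stays in the output, flagged, with missing values
  far <- age_stratified_shap(sh, gen$table, breaks = c(50, 101, 105, 110))
  empty_rows <- far[far$age_bin == "101-105", ]
  expect_true(all(empty_rows$unstable))
  expect_true(all(is.na(empty_rows$mean_abs_shap)))
  expect_error(age_stratified_shap(sh, gen$table, breaks = c(50, 70, 60)),
               "increasing")
})

test_that("calibrate_ranking aligns cohorts on the reference order", {
  mk <- function(features, values) {
    structure(data.frame(feature = features, mean_abs_shap = values,
                         rank = seq_along(features),
                         above_threshold = values > 0.1),
              scale = "log_odds", base_value = 0,
              class = c("shap_summary", "data.frame"))
  }
  ref <- mk(c("age", "female", "income"), c(2, 1, 0.5))
  same <- mk(c("age", "female", "income"), c(2, 1, 0.5))
  other <- mk(c("female", "smoking", "age"), c(0.9, 0.7, 0.4))
  tab <- calibrate_ranking(list(usa = ref, twin = same, eu = other))
  expect_equal(tab$feature, c("age", "female", "income", "smoking"))
  expect_equal(tab$rank_twin[1:3], 1:3)
  expect_true(is.na(tab$rank_eu[tab$feature == "income"]))
  expect_true(is.na(tab$rank_usa[tab$feature == "smoking"]))
  disjoint <- mk(c("x1", "x2"), c(1, 0.5))
  expect_error(calibrate_ranking(list(a = ref, b = disjoint)),
               "no features")
})
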