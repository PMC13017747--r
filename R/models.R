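# Classifier suite: 12 base learners, the age+gender logistic benchmark,
# and the Super Learner stacking ensemble. All fits are deterministic
# given (spec, data): every stochastic component is seeded from the model
# spec and runs single-threaded.

MODEL_NAMES <- c("ridge_logistic", "knn", "logistic", "decision_tree",
                 "svm", "naive_bayes", "adaboost", "bagging",
                 "random_forest", "extra_trees", "gbm_leafwise", "xgboost",
                 "benchmark", "super_learner")

# Models that consume missing values natively (no imputation/scaling).
BOOSTED_MODELS <- c("gbm_leafwise", "xgboost")

#' Model specification
#'
#' @param name one of `"ridge_logistic"` (L2-penalized linear classifier),
#'   `"knn"`, `"logistic"`, `"decision_tree"`, `"svm"`, `"naive_bayes"`,
#'   `"adaboost"` (discrete AdaBoost over depth-1 trees), `"bagging"`
#'   (bagged trees: random forest with mtry = number of features),
#'   `"random_forest"`, `"extra_trees"`, `"gbm_leafwise"` (leaf-wise
#'   gradient-boosted trees, 31 leaves, learning rate 0.1, 100 rounds),
#'   `"xgboost"` (depth-wise gradient boosting), `"benchmark"` (logistic
#'   regression on age and gender only), `"super_learner"`.
#' @param hyperparams named list overriding the documented defaults.
#' @param seed integer seed for any stochastic component of the fit.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, hyperparams = list(), seed = 1L) {
  name <- match.arg(name, MODEL_NAMES)
  structure(list(name = name, hyperparams = hyperparams,
                 seed = as.integer(seed)),
            class = "md_model_spec")
}

#' The default 12-classifier suite
#'
#' @param seed integer seed shared by all specs.
#' @return Named list of [model_spec()] objects for the 12 base learners.
#' @export
default_model_specs <- function(seed = 1L) {
  nm <- setdiff(MODEL_NAMES, c("benchmark", "super_learner"))
  stats::setNames(lapply(nm, model_spec, seed = seed), nm)
}

default_hyperparams <- function(name) {
  switch(name,
    ridge_logistic = list(lambda = 1e-3),
    knn = list(k = 25),
    logistic = list(),
    decision_tree = list(cp = 0.001, minbucket = 20),
    svm = list(kernel = "radial", cost = 1, max_train = 10000),
    naive_bayes = list(laplace = 0),
    adaboost = list(n_rounds = 50),
    bagging = list(num_trees = 200),
    random_forest = list(num_trees = 200),
    extra_trees = list(num_trees = 200),
    gbm_leafwise = list(nrounds = 100, eta = 0.1, max_leaves = 31,
                        min_child_weight = 1),
    xgboost = list(nrounds = 100, eta = 0.3, max_depth = 6),
    benchmark = list(),
    list())
}

resolve_hyperparams <- function(spec) {
  hp <- default_hyperparams(spec$name)
  hp[names(spec$hyperparams)] <- spec$hyperparams
  hp
}

# Preprocessing fitted on train only: per-column median imputation and
# standardization (constant columns get scale 1).
fit_preprocess <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  Xi <- impute_cols(X, med)
  ctr <- colMeans(Xi)
  scl <- apply(Xi, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(medians = med, center = ctr, scale = scl)
}

impute_cols <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  X
}

apply_preprocess <- function(prep, X) {
  X <- impute_cols(X, prep$medians)
  sweep(sweep(X, 2, prep$center, "-"), 2, prep$scale, "/")
}

xgb_params <- function(name, hp, seed) {
  base <- list(objective = "binary:logistic", nthread = 1,
               seed = as.integer(seed %% .Machine$integer.max))
  if (name == "gbm_leafwise") {
    c(base, list(tree_method = "hist", grow_policy = "lossguide",
                 max_leaves = hp$max_leaves, max_depth = 0,
                 eta = hp$eta, min_child_weight = hp$min_child_weight))
  } else {
    c(base, list(tree_method = "hist", max_depth = hp$max_depth,
                 eta = hp$eta))
  }
}

#' Fit one classifier on a cohort's training rows
#'
#' Preprocessing (median imputation fitted on train, standardization) is
#' applied for all models except the gradient-boosted trees, which consume
#' missing values natively. The fit is deterministic given
#' (spec, train, feature_subset).
#'
#' @param spec a [model_spec()].
#' @param train training `cohort_table` (both outcome classes required).
#' @param feature_subset feature columns to use (default: all).
#' @return An object of class `fitted_model` with elements `spec`,
#'   `feature_names`, `prep`, `handle` (opaque fitted estimator) and
#'   `hyperparams` (fully resolved).
#' @export
fit_model <- function(spec, train, feature_subset = feature_names(train)) {
  stopifnot(inherits(spec, "md_model_spec"))
  if (length(feature_subset) == 0L) {
    stop("feature_subset must be non-empty", call. = FALSE)
  }
  y <- outcomes(train)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single outcome class", call. = FALSE)
  }
  if (spec$name == "super_learner") {
    stop("use fit_super_learner() for the stacking ensemble", call. = FALSE)
  }
  X <- feature_matrix(train, feature_subset)
  hp <- resolve_hyperparams(spec)
  bump_fit_counter()

  if (spec$name %in% BOOSTED_MODELS) {
    prep <- NULL
    handle <- with_seed(spec$seed, {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, missing = NA)
      xgboost::xgb.train(params = xgb_params(spec$name, hp, spec$seed),
                         data = dtrain, nrounds = hp$nrounds, verbose = 0)
    })
  } else {
    prep <- fit_preprocess(X)
    Z <- apply_preprocess(prep, X)
    handle <- with_seed(spec$seed, fit_base_handle(spec$name, hp, Z, y))
  }
  structure(list(spec = spec, feature_names = feature_subset, prep = prep,
                 handle = handle, hyperparams = hp),
            class = "fitted_model")
}

fit_base_handle <- function(name, hp, Z, y) {
  switch(name,
    logistic = , benchmark = {
      df <- as.data.frame(Z)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    ridge_logistic = glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                                    lambda = hp$lambda, standardize = FALSE),
    knn = list(train = Z, labels = y, k = hp$k),
    decision_tree = {
      df <- as.data.frame(Z)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minbucket = hp$minbucket))
    },
    svm = fit_svm_platt(Z, y, hp),
    naive_bayes = e1071::naiveBayes(as.data.frame(Z),
                                    factor(y, levels = c(0, 1)),
                                    laplace = hp$laplace),
    adaboost = fit_adaboost(Z, y, hp$n_rounds),
    bagging = ranger::ranger(x = as.data.frame(Z),
                             y = factor(y, levels = c(0, 1)),
                             num.trees = hp$num_trees, mtry = ncol(Z),
                             probability = TRUE, num.threads = 1,
                             seed = sample.int(.Machine$integer.max, 1)),
    random_forest = ranger::ranger(x = as.data.frame(Z),
                                   y = factor(y, levels = c(0, 1)),
                                   num.trees = hp$num_trees,
                                   probability = TRUE, num.threads = 1,
                                   seed = sample.int(.Machine$integer.max, 1)),
    extra_trees = ranger::ranger(x = as.data.frame(Z),
                                 y = factor(y, levels = c(0, 1)),
                                 num.trees = hp$num_trees,
                                 splitrule = "extratrees",
                                 num.random.splits = 1,
                                 probability = TRUE, num.threads = 1,
                                 seed = sample.int(.Machine$integer.max, 1)),
    stop("unknown model name: ", name, call. = FALSE))
}

# SVM with deterministic Platt-style probability calibration: the margin
# scores on the training rows are mapped through a logistic sigmoid fitted
# by glm (libsvm's internal calibration shuffles rows unreproducibly).
fit_svm_platt <- function(Z, y, hp) {
  n <- nrow(Z)
  idx <- if (n > hp$max_train) sample.int(n, hp$max_train) else seq_len(n)
  fit <- e1071::svm(Z[idx, , drop = FALSE], factor(y[idx], levels = c(0, 1)),
                    kernel = hp$kernel, cost = hp$cost, probability = FALSE,
                    scale = FALSE)
  dvm <- attr(stats::predict(fit, Z, decision.values = TRUE),
              "decision.values")
  dv <- dvm[, 1L]
  # orient decision values so larger = class "1" (death)
  sgn <- if (startsWith(colnames(dvm)[1L], "0/")) -1 else 1
  platt <- suppressWarnings(stats::glm(y ~ s,
                                       data = data.frame(y = y, s = sgn * dv),
                                       family = stats::binomial()))
  list(svm = fit, platt = platt, sign = sgn)
}

# Discrete AdaBoost.M1 with depth-1 rpart stumps; probabilities via the
# standard logistic link on the additive score, p = 1/(1 + exp(-2F)).
fit_adaboost <- function(Z, y, n_rounds) {
  n <- nrow(Z)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1, 1, -1)
  df <- as.data.frame(Z)
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {
    stumps <- list(NULL); alphas <- 0
  }
  list(stumps = stumps, alphas = alphas, p1 = mean(y))
}

predict_adaboost <- function(handle, Z) {
  if (is.null(handle$stumps[[1L]])) return(rep(handle$p1, nrow(Z)))
  df <- as.data.frame(Z)
  F <- rep(0, nrow(Z))
  for (m in seq_along(handle$stumps)) {
    pred <- ifelse(stats::predict(handle$stumps[[m]], df,
                                  type = "class") == "1", 1, -1)
    F <- F + handle$alphas[m] * pred
  }
  1 / (1 + exp(-2 * F))
}

#' Predict death probabilities from a fitted model
#'
#' Columns are aligned by name; the input may hold the model's features in
#' any order (extra columns are ignored, missing ones raise an error
#' naming them).
#'
#' @param model a `fitted_model` (or `fitted_super_learner`).
#' @param table a `cohort_table` (or data.frame containing the model's
#'   feature columns).
#' @return Numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predict_proba <- function(model, table) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.fitted_model <- function(model, table) {
  X <- if (inherits(table, "cohort_table")) {
    feature_matrix(table, model$feature_names)
  } else {
    absent <- setdiff(model$feature_names, colnames(table))
    if (length(absent) > 0L) {
      stop("prediction input lacks feature column(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    as.matrix(as.data.frame(table)[, model$feature_names, drop = FALSE])
  }
  name <- model$spec$name
  if (name %in% BOOSTED_MODELS) {
    p <- stats::predict(model$handle, xgboost::xgb.DMatrix(X, missing = NA))
    return(as.numeric(p))
  }
  Z <- apply_preprocess(model$prep, X)
  h <- model$handle
  p <- switch(name,
    logistic = , benchmark =
      as.numeric(suppressWarnings(
        stats::predict(h, as.data.frame(Z), type = "response"))),
    ridge_logistic =
      as.numeric(stats::predict(h, Z, type = "response")[, 1L]),
    knn = with_seed(model$spec$seed, {
      pred <- class::knn(h$train, Z, factor(h$labels, levels = c(0, 1)),
                         k = h$k, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    }),
    decision_tree =
      stats::predict(h, as.data.frame(Z), type = "prob")[, "1"],
    svm = {
      dv <- attr(stats::predict(h$svm, Z, decision.values = TRUE),
                 "decision.values")[, 1L]
      as.numeric(stats::predict(h$platt,
                                data.frame(s = h$sign * dv),
                                type = "response"))
    },
    naive_bayes =
      stats::predict(h, as.data.frame(Z), type = "raw")[, "1"],
    adaboost = predict_adaboost(h, Z),
    bagging = , random_forest = , extra_trees =
      stats::predict(h, data = as.data.frame(Z),
                     num.threads = 1)$predictions[, "1"],
    stop("unknown model name: ", name, call. = FALSE))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Fit the demographic benchmark model
#'
#' Logistic regression on exactly the age and gender columns — the
#' conventional null model against which the value of the remaining risk
#' factors is judged.
#'
#' @param train training `cohort_table`.
#' @param seed integer seed (the fit itself is deterministic).
#' @return A `fitted_model` whose `feature_names` are `c(age, gender)`.
#' @export
fit_benchmark <- function(train, seed = 1L) {
  cols <- c(attr(train, "age_col"), attr(train, "gender_col"))
  absent <- setdiff(cols, names(train))
  if (length(absent) > 0L) {
    stop("benchmark requires demographic column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  fit_model(model_spec("benchmark", seed = seed), train, cols)
}

# Stratified k-fold assignment (by outcome), deterministic given seed.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit the Super Learner stacking ensemble
#'
#' Classical stacking: each base learner's out-of-fold predictions (from
#' stratified k-fold cross-validation on the training set) form the
#' meta-level design; the meta-learner is the convex combination
#' (non-negative weights summing to 1) minimizing Bernoulli log-loss,
#' found by quasi-Newton optimization of a softmax parameterization. Base
#' learners are refit on the full training set for deployment.
#'
#' @param base_specs list of at least 2 [model_spec()]s (use a single spec
#'   for the degenerate weight-1 case).
#' @param train training `cohort_table`.
#' @param k_folds number of cross-validation folds (>= 2).
#' @param seed integer seed controlling fold assignment and base fits.
#' @return An object of class `fitted_super_learner` with elements
#'   `bases` (refitted models), `weights`, `oof_logloss` (per base) and
#'   `feature_names`.
#' @export
fit_super_learner <- function(base_specs, train, k_folds = 5, seed = 1L) {
  stopifnot(k_folds >= 2, length(base_specs) >= 1L)
  y <- outcomes(train)
  if (min(table(y)) < k_folds) {
    stop("cannot form ", k_folds, " stratified folds: minority class has ",
         min(table(y)), " rows", call. = FALSE)
  }
  fold <- stratified_folds(y, k_folds, child_seed(seed, "sl_folds"))
  n <- nrow(train); m <- length(base_specs)
  Z <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    sp <- base_specs[[j]]
    sp$seed <- child_seed(seed, paste0("sl_base_", j))
    for (f in seq_len(k_folds)) {
      tr <- subset_rows(train, which(fold != f))
      fit <- fit_model(sp, tr)
      Z[fold == f, j] <- predict_proba(fit, subset_rows(train,
                                                        which(fold == f)))
    }
  }
  w <- solve_convex_logloss_weights(y, Z)
  bases <- lapply(seq_len(m), function(j) {
    sp <- base_specs[[j]]
    sp$seed <- child_seed(seed, paste0("sl_base_", j))
    fit_model(sp, train)
  })
  oof_ll <- apply(Z, 2, function(p) -mean_bernoulli_loglik(y, p))
  structure(list(bases = bases, weights = w, oof_logloss = oof_ll,
                 feature_names = feature_names(train),
                 spec = model_spec("super_learner", seed = seed)),
            class = c("fitted_super_learner", "fitted_model_like"))
}

# Convex log-loss-minimizing weights over the simplex via softmax
# reparameterization; deterministic (equal-weight initialization).
solve_convex_logloss_weights <- function(y, Z) {
  m <- ncol(Z)
  if (m == 1L) return(1)
  Zc <- clip_prob(Z)
  nll <- function(theta) {
    w <- exp(c(0, theta)); w <- w / sum(w)
    p <- clip_prob(drop(Zc %*% w))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- stats::optim(rep(0, m - 1L), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  w <- exp(c(0, opt$par)); w <- w / sum(w)
  unname(w)
}

#' @export
predict_proba.fitted_super_learner <- function(model, table) {
  P <- vapply(model$bases, predict_proba, numeric(nrow(table)), table = table)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  drop(P %*% model$weights)
}

#' Evaluate a model suite across seed replications
#'
#' For each seed: split the cohort, fit every spec (plus the demographic
#' benchmark), and compute the five evaluation metrics on the test set;
#' per-seed values are aggregated into a [aggregate_report()] with the
#' mean test-set prevalence as the IP row.
#'
#' @param specs named list of [model_spec()]s.
#' @param cohort a `cohort_table`.
#' @param split split parameters ([split_spec()]); its seed field is
#'   replaced by each replication seed.
#' @param seeds integer vector of replication seeds.
#' @param include_benchmark also fit the age+gender benchmark
#'   (default TRUE).
#' @param imv_baseline `"prevalence"` (default) scores each model's IMV
#'   against the prevalence-constant predictor; `"benchmark"` scores it
#'   against the demographic benchmark's predictions.
#' @return A `metric_report`.
#' @export
evaluate_suite <- function(specs, cohort, split = split_spec(),
                           seeds = 1:10, include_benchmark = TRUE,
                           imv_baseline = c("prevalence", "benchmark")) {
  imv_baseline <- match.arg(imv_baseline)
  stopifnot(length(seeds) >= 1L)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$name, character(1))
  }
  rows <- list(); ip <- numeric(0)
  for (sd in seeds) {
    split$seed <- as.integer(sd)
    parts <- split_cohort(cohort, split)
    y_test <- outcomes(parts$test)
    ip <- c(ip, mean(y_test))
    bench <- if (include_benchmark || imv_baseline == "benchmark") {
      fit_benchmark(parts$train, seed = child_seed(sd, "benchmark"))
    } else NULL
    p_base <- if (imv_baseline == "benchmark") {
      predict_proba(bench, parts$test)
    } else prevalence_baseline(y_test)
    eval_one <- function(nm, p) {
      vals <- metric_set(y_test, p, p_baseline = p_base)
      data.frame(model = nm, metric = names(vals), seed = sd,
                 value = unname(vals), stringsAsFactors = FALSE)
    }
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      sp$seed <- child_seed(sd, paste0("fit_", nm))
      fit <- fit_model(sp, parts$train)
      rows[[length(rows) + 1L]] <- eval_one(nm, predict_proba(fit, parts$test))
    }
    if (include_benchmark) {
      rows[[length(rows) + 1L]] <-
        eval_one("benchmark", predict_proba(bench, parts$test))
    }
  }
  aggregate_report(do.call(rbind, rows), in_sample_prevalence = ip)
}

# Fit counter (used to assert coalition caching performs no refits).
.mortdomains_state <- new.env(parent = emptyenv())
.mortdomains_state$fit_count <- 0L

bump_fit_counter <- function() {
  .mortdomains_state$fit_count <- .mortdomains_state$fit_count + 1L
}

#' Number of model fits performed in this session
#'
#' Diagnostic counter used to verify coalition-value caching; reset with
#' `reset = TRUE`.
#'
#' @param reset reset the counter to zero.
#' @return Integer count (before any reset).
#' @export
fit_count <- function(reset = FALSE) {
  n <- .mortdomains_state$fit_count
  if (reset) .mortdomains_state$fit_count <- 0L
  n
}
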