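# Per-feature attribution of model predictions (SHAP), aggregated as
# mean |SHAP| summaries overall and stratified by age group.
#
# Tree-ensemble models get exact path-dependent TreeSHAP on the log-odds
# margin scale (the scale on which mean |SHAP| thresholds are defined;
# attributions on a probability scale are bounded by 1 and cannot
# reproduce the >1 values that age attains in strongly age-driven
# cohorts). Any other model falls back to interventional Shapley values
# against a background sample: exact coalition enumeration up to 12
# features, permutation sampling above that.

#' Compute per-individual SHAP attributions
#'
#' For gradient-boosted tree models this is exact path-dependent TreeSHAP
#' (via the booster's own attribution pass), satisfying local accuracy to
#' float precision: for every row, `base_value + sum(attributions)`
#' equals the model's margin (log-odds) output. For other models an
#' interventional Shapley value is computed against `background`: exact
#' enumeration of all feature coalitions for p <= 12, permutation
#' sampling (at least `2p + 2048` model evaluations per row, fixed seed)
#' for 12 < p <= 100. Attributions are conventionally computed over the
#' full cohort (train plus test) so the summary reflects both fitting and
#' generalization behavior.
#'
#' @param model a `fitted_model`.
#' @param table `cohort_table` (or data.frame) of rows to attribute.
#' @param method `"auto"` (tree attribution when available), `"tree"`,
#'   `"exact"` or `"sampling"`.
#' @param scale `"log_odds"` (default) or `"probability"`; the
#'   probability scale is only available through the model-agnostic
#'   methods and is not comparable with the 0.1 mean-|SHAP| reporting
#'   threshold.
#' @param background background rows for the model-agnostic methods
#'   (default: up to 100 rows sampled from `table` with `seed`).
#' @param seed seed for background sampling / permutation draws.
#' @param n_permutations permutation count for `"sampling"`; default
#'   chosen so the evaluation budget is at least `2p + 2048`.
#' @return An object of class `shap_matrix`: list with `attributions`
#'   (n x p matrix), `base_value`, `feature_names`, `scale`.
#' @export
compute_shap <- function(model, table,
                         method = c("auto", "tree", "exact", "sampling"),
                         scale = c("log_odds", "probability"),
                         background = NULL, seed = 1L,
                         n_permutations = NULL) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  is_tree <- inherits(model, "fitted_model") &&
    model$spec$name %in% BOOSTED_MODELS
  if (method == "auto") method <- if (is_tree) "tree" else "exact"
  p <- length(model$feature_names)
  if (method == "tree") {
    if (!is_tree) {
      stop("tree attribution requires a gradient-boosted tree model",
           call. = FALSE)
    }
    if (scale != "log_odds") {
      stop("tree attribution is defined on the log-odds margin scale; ",
           "use method = 'exact' for probability-scale attributions",
           call. = FALSE)
    }
    X <- feature_matrix(table, model$feature_names)
    contrib <- tree_shap_matrix(model, X)
    attr_mat <- contrib[, seq_len(p), drop = FALSE]
    colnames(attr_mat) <- model$feature_names
    return(structure(list(attributions = attr_mat,
                          base_value = unname(contrib[1L, p + 1L]),
                          feature_names = model$feature_names,
                          scale = "log_odds"),
                     class = "shap_matrix"))
  }
  if (method == "exact" && p > 12L) {
    method <- "sampling"
  }
  if (p > 100L) {
    stop("model-agnostic attribution is capped at 100 features; ",
         "subsample or group features first", call. = FALSE)
  }
  X <- feature_matrix(table, model$feature_names)
  if (is.null(background)) {
    idx <- with_seed(child_seed(seed, "shap_bg"),
                     sample.int(nrow(X), min(100L, nrow(X))))
    background <- X[idx, , drop = FALSE]
  } else {
    background <- feature_matrix(background, model$feature_names)
  }
  f <- make_value_fun(model, scale)
  base_value <- mean(f(background))
  attr_mat <- if (method == "exact") {
    shap_exact(f, X, background)
  } else {
    if (is.null(n_permutations)) {
      n_permutations <- max(10L, ceiling((2 * p + 2048) / (p + 1)))
    }
    shap_sampling(f, X, background, n_permutations,
                  child_seed(seed, "shap_perm"))
  }
  colnames(attr_mat) <- model$feature_names
  structure(list(attributions = attr_mat, base_value = base_value,
                 feature_names = model$feature_names, scale = scale),
            class = "shap_matrix")
}

make_value_fun <- function(model, scale) {
  fn <- model$feature_names
  function(M) {
    df <- as.data.frame(M)
    names(df) <- fn
    pr <- predict_proba(model, df)
    if (scale == "log_odds") logit(clip_prob(pr, 1e-7)) else pr
  }
}

# Interventional value of coalition S for row x: average model output
# with S taken from x and the rest from each background row.
coalition_payoff <- function(f, x, background, S) {
  M <- background
  if (length(S) > 0L) M[, S] <- matrix(x[S], nrow(M), length(S), byrow = TRUE)
  mean(f(M))
}

shap_exact <- function(f, X, background) {
  p <- ncol(X); n <- nrow(X)
  subsets <- lapply(0:(2^p - 1), function(code) which(bitwAnd(
    code, 2^(seq_len(p) - 1)) > 0))
  sizes <- lengths(subsets)
  # Shapley coefficient |S|! (p-|S|-1)! / p!; the full set never appears
  # as an S in the marginal sums, so its slot is inert
  w <- ifelse(sizes < p,
              factorial(sizes) * factorial(pmax(p - sizes - 1, 0)) /
                factorial(p), 0)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    v <- vapply(subsets, coalition_payoff, numeric(1),
                f = f, x = X[i, ], background = background)
    names(v) <- vapply(subsets, paste, character(1), collapse = ",")
    for (j in seq_len(p)) {
      without_j <- which(vapply(subsets, function(S) !(j %in% S),
                                logical(1)))
      for (k in without_j) {
        S <- subsets[[k]]
        key_with <- paste(sort(c(S, j)), collapse = ",")
        out[i, j] <- out[i, j] + w[k] * (v[[key_with]] - v[[k]])
      }
    }
  }
  out
}

shap_sampling <- function(f, X, background, n_permutations, seed) {
  p <- ncol(X); n <- nrow(X)
  perms <- with_seed(seed, lapply(seq_len(n_permutations),
                                  function(i) sample.int(p)))
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    x <- X[i, ]
    for (perm in perms) {
      prev <- coalition_payoff(f, x, background, integer(0))
      S <- integer(0)
      for (j in perm) {
        S <- c(S, j)
        cur <- coalition_payoff(f, x, background, S)
        out[i, j] <- out[i, j] + (cur - prev)
        prev <- cur
      }
    }
  }
  out / n_permutations
}

#' Check SHAP local accuracy against model margins
#'
#' @param shap a `shap_matrix`.
#' @param margins model outputs on the attribution scale, one per row.
#' @return Maximum absolute discrepancy
#'   `|base_value + rowSums(attributions) - margins|`.
#' @export
local_accuracy_error <- function(shap, margins) {
  max(abs(shap$base_value + rowSums(shap$attributions) - margins))
}

#' Margin (log-odds) predictions of a fitted model
#'
#' @param model a `fitted_model`.
#' @param table rows to predict.
#' @return Numeric vector of log-odds outputs (for boosted trees a
#'   double-precision traversal of the fitted trees, so attribution
#'   sums can be compared against it at strict tolerance; logit of
#'   clipped probability otherwise).
#' @export
predict_margin <- function(model, table) {
  if (inherits(model, "fitted_model") && model$spec$name %in% BOOSTED_MODELS) {
    X <- feature_matrix(table, model$feature_names)
    tree_margin(model, X)
  } else {
    logit(clip_prob(predict_proba(model, table), 1e-7))
  }
}

#' Mean absolute SHAP summary
#'
#' Per-feature mean of absolute attributions, ranked in decreasing order
#' with alphabetical tie-breaking, plus the conventional stability
#' threshold mask (mean |SHAP| > 0.1 on the log-odds scale).
#'
#' @param shap a `shap_matrix`.
#' @param threshold stability threshold (default 0.1).
#' @return A `shap_summary` data.frame with columns `feature`,
#'   `mean_abs_shap`, `rank`, `above_threshold`; attributes `scale` and
#'   `base_value`.
#' @export
mean_abs_shap <- function(shap, threshold = 0.1) {
  stopifnot(inherits(shap, "shap_matrix"), nrow(shap$attributions) > 0L)
  m <- colMeans(abs(shap$attributions))
  ord <- order(-m, names(m))
  out <- data.frame(feature = names(m)[ord],
                    mean_abs_shap = unname(m[ord]),
                    rank = seq_along(m),
                    above_threshold = unname(m[ord]) > threshold,
                    stringsAsFactors = FALSE)
  structure(out, scale = shap$scale, base_value = shap$base_value,
            threshold = threshold,
            class = c("shap_summary", "data.frame"))
}

#' Top-ranked risk factors by mean |SHAP|
#'
#' @param summary a `shap_summary`.
#' @param threshold report only features with mean |SHAP| strictly above
#'   this value (default 0.1).
#' @return Character vector of features in rank order (possibly empty).
#' @export
top_factors <- function(summary, threshold = 0.1) {
  stopifnot(threshold >= 0)
  if (!identical(attr(summary, "scale"), "log_odds") && threshold > 0) {
    warning("mean |SHAP| threshold is defined on the log-odds scale; ",
            "summary is on scale '", attr(summary, "scale"), "'")
  }
  summary$feature[summary$mean_abs_shap > threshold]
}

#' Age-stratified mean |SHAP| summary
#'
#' Mean absolute attribution per feature within each age bin. Bins are
#' half-open `[lo, hi)` with the final bin closed; bins with fewer than
#' 30 individuals are flagged unstable, empty bins are kept with missing
#' values.
#'
#' @param shap a `shap_matrix` computed on `table`'s rows (same order).
#' @param table the `cohort_table` the attributions belong to.
#' @param breaks increasing numeric vector of bin edges; default 5-year
#'   bins from 50 to 80 plus a single 80+ bin.
#' @return A `shap_age_summary` data.frame: `age_bin`, `feature`,
#'   `mean_abs_shap`, `n`, `unstable`.
#' @export
age_stratified_shap <- function(shap, table,
                                breaks = c(seq(50, 80, by = 5), 110)) {
  stopifnot(inherits(shap, "shap_matrix"),
            nrow(shap$attributions) == nrow(table))
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("age bins must be strictly increasing (non-overlapping)",
         call. = FALSE)
  }
  age <- table[[attr(table, "age_col")]]
  labs <- paste0(utils::head(breaks, -1), "-", utils::tail(breaks, -1))
  labs[length(labs)] <- paste0(breaks[length(breaks) - 1], "+")
  bin <- cut(age, breaks = breaks, right = FALSE, include.lowest = TRUE,
             labels = labs)
  rows <- lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    if (length(idx) == 0L) {
      data.frame(age_bin = b, feature = shap$feature_names,
                 mean_abs_shap = NA_real_, n = 0L, unstable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      m <- colMeans(abs(shap$attributions[idx, , drop = FALSE]))
      data.frame(age_bin = b, feature = names(m),
                 mean_abs_shap = unname(m), n = length(idx),
                 unstable = length(idx) < 30L, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, scale = shap$scale,
            class = c("shap_age_summary", "data.frame"))
}

#' Align several SHAP summaries on a reference cohort's ranking
#'
#' Cross-cohort comparison table: rows are features ordered by their rank
#' in the reference summary (features absent from the reference appended
#' in their own rank order); each summary contributes a rank and
#' mean-|SHAP| column, with missing cells for features a cohort lacks.
#'
#' @param summaries named list of `shap_summary` objects.
#' @param reference index or name of the reference summary (default 1).
#' @return data.frame with `feature` plus `rank_*` and `shap_*` columns
#'   per summary.
#' @export
calibrate_ranking <- function(summaries, reference = 1L) {
  stopifnot(length(summaries) >= 1L)
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    names(summaries) <- paste0("cohort", seq_along(summaries))
  }
  ref <- summaries[[reference]]
  shared <- lapply(summaries, function(s) intersect(s$feature, ref$feature))
  if (any(lengths(shared) == 0L)) {
    stop("a summary shares no features with the reference", call. = FALSE)
  }
  extra <- setdiff(unique(unlist(lapply(summaries, `[[`, "feature"))),
                   ref$feature)
  features <- c(ref$feature, extra)
  out <- data.frame(feature = features, stringsAsFactors = FALSE)
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    i <- match(features, s$feature)
    out[[paste0("rank_", nm)]] <- s$rank[i]
    out[[paste0("shap_", nm)]] <- s$mean_abs_shap[i]
  }
  out
}
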