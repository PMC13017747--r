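# Evaluation metrics for binary death prediction: ROC-AUC, PR-AUC
# (average precision), Efron R-squared, and the Inter-Model Vigorish.

check_binary <- function(y) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  y
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a randomly chosen positive receives a higher score than a randomly
#' chosen negative, ties counted one half. Invariant under strictly
#' monotone transformations of the scores.
#'
#' @param y binary outcome vector (both classes required).
#' @param p score/probability vector aligned with `y`.
#' @return ROC-AUC in \[0, 1\].
#' @export
roc_auc <- function(y, p) {
  check_binary(y)
  stopifnot(length(y) == length(p), !anyNA(p))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("roc_auc requires both outcome classes", call. = FALSE)
  }
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision form with step interpolation: sum over descending
#' distinct score thresholds of (recall increment) x (precision at that
#' threshold). The no-skill baseline of this metric is the outcome
#' prevalence: a constant predictor scores exactly the prevalence.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(y, p) {
  check_binary(y)
  stopifnot(length(y) == length(p), !anyNA(p))
  n_pos <- sum(y == 1)
  if (n_pos == 0L) stop("pr_auc requires at least one positive", call. = FALSE)
  o <- order(p, decreasing = TRUE)
  y_sorted <- y[o]; p_sorted <- p[o]
  # indices of the last element of each distinct-score block
  last <- cumsum(rle(p_sorted)$lengths)
  tp <- cumsum(y_sorted)[last]
  fp <- (last - cumsum(y_sorted)[last])
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Efron R-squared for binary outcomes
#'
#' `1 - sum((y - p)^2) / sum((y - mean(y))^2)`, computed on predicted
#' probabilities. [pseudo_r2()] is Efron's pseudo-R-squared, which is the
#' same quantity on probability predictions; both are exposed because
#' evaluation reports conventionally list them as separate columns, and
#' they agree to machine precision.
#'
#' @inheritParams roc_auc
#' @return R-squared (can be negative for a predictor worse than the mean).
#' @export
r2_binary <- function(y, p) {
  check_binary(y)
  stopifnot(length(y) == length(p), !anyNA(p))
  if (length(unique(y)) < 2L) {
    stop("r2 undefined for a constant outcome", call. = FALSE)
  }
  1 - sum((y - p)^2) / sum((y - mean(y))^2)
}

#' @rdname r2_binary
#' @export
pseudo_r2 <- function(y, p) {
  check_binary(y)
  stopifnot(length(y) == length(p), !anyNA(p))
  if (length(unique(y)) < 2L) {
    stop("pseudo-R2 undefined for a constant outcome", call. = FALSE)
  }
  ybar <- mean(y)
  sse <- sum((y - p)^2)
  sst <- sum((y - ybar)^2)
  1 - sse / sst
}

#' Entropy-equivalent winning probability
#'
#' Maps a mean Bernoulli log-likelihood to the unique `w` in \[0.5, 1)
#' whose symmetric Bernoulli entropy equals it:
#' `w*log(w) + (1-w)*log(1-w) = mean_loglik`. This is the "bet-winning"
#' probability underlying the Inter-Model Vigorish. Solved by bisection to
#' `|dw| < 1e-10`. Mean log-likelihoods below `log(0.5)` (worse than a
#' coin flip) are clipped to `log(0.5)`, giving `w = 0.5`.
#'
#' @param mean_loglik mean Bernoulli log-likelihood per observation
#'   (must be negative).
#' @return `w` in \[0.5, 1).
#' @export
entropy_equivalent_w <- function(mean_loglik) {
  if (!is.finite(mean_loglik) || mean_loglik >= 0) {
    stop("mean log-likelihood must be finite and negative", call. = FALSE)
  }
  target <- max(mean_loglik, log(0.5))
  ent <- function(w) w * log(w) + (1 - w) * log(1 - w)
  lo <- 0.5; hi <- 1 - 1e-16
  # ent is increasing in w on [0.5, 1): ent(0.5) = log(0.5), ent -> 0
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (ent(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

mean_bernoulli_loglik <- function(y, p, eps = 1e-12) {
  p <- clip_prob(p, eps)
  mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Inter-Model Vigorish (IMV)
#'
#' Relative gain in the entropy-equivalent winning probability of an
#' enhanced prediction over a baseline: `(w1 - w0) / w0`, where `w0`, `w1`
#' solve the entropy equation for the baseline and enhanced mean
#' log-likelihoods. Probabilities are clipped to `[1e-12, 1 - 1e-12]`
#' before taking logs. When a model is reported alone, the conventional
#' baseline is the prevalence-constant predictor on the same test set
#' (see [prevalence_baseline()]).
#'
#' @param y binary outcome vector.
#' @param p_baseline baseline probability vector.
#' @param p_enhanced enhanced-model probability vector.
#' @return IMV score (0 for self-comparison; positive when the enhanced
#'   model fits better).
#' @export
imv <- function(y, p_baseline, p_enhanced) {
  check_binary(y)
  stopifnot(length(p_baseline) == length(y), length(p_enhanced) == length(y))
  w0 <- entropy_equivalent_w(mean_bernoulli_loglik(y, p_baseline))
  w1 <- entropy_equivalent_w(mean_bernoulli_loglik(y, p_enhanced))
  (w1 - w0) / w0
}

#' Prevalence-constant baseline predictions
#'
#' @param y binary outcome vector defining the prevalence.
#' @param n number of predictions to emit (default `length(y)`).
#' @return Numeric vector repeating `mean(y)`.
#' @export
prevalence_baseline <- function(y, n = length(y)) rep(mean(y), n)

#' Compute the full metric set for one model on one test set
#'
#' @param y binary test outcomes.
#' @param p predicted probabilities.
#' @param p_baseline baseline probabilities for the IMV (default: the
#'   prevalence-constant predictor built from `y`).
#' @return Named numeric vector with entries `roc_auc`, `pr_auc`, `r2`,
#'   `pseudo_r2`, `imv`.
#' @export
metric_set <- function(y, p, p_baseline = prevalence_baseline(y)) {
  c(roc_auc = roc_auc(y, p),
    pr_auc = pr_auc(y, p),
    r2 = r2_binary(y, p),
    pseudo_r2 = pseudo_r2(y, p),
    imv = imv(y, p_baseline, p))
}

#' Aggregate per-seed metric values into a report
#'
#' The seed-replication report: per (model, metric), the mean and standard
#' error (sample SD across seeds / sqrt(number of seeds); 0 for a single
#' seed) of the per-seed values, plus the in-sample prevalence row (mean
#' test-set prevalence across seeds).
#'
#' @param per_seed data.frame with columns `model`, `metric`, `seed`,
#'   `value`.
#' @param in_sample_prevalence per-seed test-set prevalences (averaged into
#'   the report's `IP` attribute).
#' @return A `metric_report`: data.frame with columns `model`, `metric`,
#'   `mean`, `se`, `n_seeds`, attribute `in_sample_prevalence`, and the
#'   raw per-seed table as attribute `per_seed`.
#' @export
aggregate_report <- function(per_seed, in_sample_prevalence = NA_real_) {
  stopifnot(all(c("model", "metric", "seed", "value") %in% names(per_seed)))
  if (nrow(per_seed) == 0L) stop("no per-seed metrics supplied", call. = FALSE)
  key <- interaction(per_seed$model, per_seed$metric, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(per_seed, key), function(g) {
    v <- g$value
    se <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
    data.frame(model = g$model[1L], metric = g$metric[1L],
               mean = mean(v), se = se, n_seeds = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$model, agg$metric), , drop = FALSE]
  structure(agg,
            in_sample_prevalence = mean(in_sample_prevalence),
            per_seed = per_seed,
            class = c("metric_report", "data.frame"))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  df <- as.data.frame(x)
  df$`mean (se)` <- sprintf("%.3f (%.3f)", df$mean, df$se)
  print(df[, c("model", "metric", "mean (se)", "n_seeds")], row.names = FALSE)
  cat(sprintf("IP (in-sample prevalence): %.3f\n",
              attr(x, "in_sample_prevalence")))
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' @param report a `metric_report`.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(rows = as.data.frame(report),
           in_sample_prevalence = attr(report, "in_sample_prevalence")),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(report)
}
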