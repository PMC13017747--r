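# Leave-one-domain-out coalition analysis: the domain-level importance of
# grouped risk factors, measured by retraining a model on every subset
# (coalition) of domains and averaging each domain's marginal metric
# contribution v(S + d) - v(S) over all coalitions S not containing d.

coalition_key <- function(members) {
  if (length(members) == 0L) return("<empty>")
  paste(sort(members), collapse = "+")
}

#' Enumerate all non-empty domain coalitions
#'
#' With D domains there are 2^D - 1 non-empty coalitions (127 for the
#' canonical 7 domains). Order is deterministic: by coalition size, then
#' lexicographically. Exhaustive enumeration is capped at D = 12.
#'
#' @param domains character vector of domain names.
#' @return List of character vectors, one per coalition.
#' @export
enumerate_coalitions <- function(domains) {
  domains <- unique(domains)
  D <- length(domains)
  if (D < 1L) stop("need at least one domain", call. = FALSE)
  if (D > 12L) {
    stop("exhaustive coalition enumeration is capped at 12 domains; ",
         "subsample domains before calling", call. = FALSE)
  }
  out <- list()
  for (size in seq_len(D)) {
    combos <- utils::combn(sort(domains), size, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Create an empty coalition ledger
#'
#' The ledger caches value-function evaluations v(S): the test-set metric
#' of a model retrained on exactly the features of coalition S. Entries
#' are keyed by the sorted domain names (plus the fitting seed), so
#' repeated queries never refit.
#'
#' @param metric_name metric being cached (e.g. `"pr_auc"`).
#' @return An object of class `coalition_ledger`.
#' @export
coalition_ledger <- function(metric_name = "pr_auc") {
  structure(list(values = new.env(parent = emptyenv()),
                 metric_name = metric_name),
            class = "coalition_ledger")
}

ledger_get <- function(ledger, key) {
  if (exists(key, envir = ledger$values, inherits = FALSE)) {
    get(key, envir = ledger$values, inherits = FALSE)
  } else NULL
}

ledger_set <- function(ledger, key, value) {
  assign(key, value, envir = ledger$values)
  invisible(value)
}

#' @export
print.coalition_ledger <- function(x, ...) {
  cat("<coalition_ledger>", length(ls(x$values)), "cached evaluations of",
      x$metric_name, "\n")
  invisible(x)
}

#' Convert a ledger to (or build one from) a named value list
#'
#' `ledger_values()` extracts all cached entries as a named numeric
#' vector; `as_coalition_ledger()` builds a ledger from such a vector
#' (names are `+`-joined sorted domain names, `"<empty>"` for v(empty)) —
#' convenient for hand-built value functions in tests and for
#' (de)serialization.
#'
#' @param ledger a `coalition_ledger`.
#' @return Named numeric vector of cached values.
#' @export
ledger_values <- function(ledger) {
  keys <- sort(ls(ledger$values))
  stats::setNames(vapply(keys, function(k) ledger_get(ledger, k),
                         numeric(1)), keys)
}

#' @rdname ledger_values
#' @param values named numeric vector of coalition values.
#' @param metric_name metric label.
#' @export
as_coalition_ledger <- function(values, metric_name = "pr_auc") {
  led <- coalition_ledger(metric_name)
  for (k in names(values)) ledger_set(led, k, unname(values[[k]]))
  led
}

#' Save / load a coalition ledger as JSON
#'
#' @param ledger a `coalition_ledger`.
#' @param path JSON file path.
#' @return `write_ledger` invisibly returns `path`; `read_ledger` returns
#'   the ledger.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(list(metric_name = ledger$metric_name,
                            values = as.list(ledger_values(ledger))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_coalition_ledger(unlist(obj$values), metric_name = obj$metric_name)
}

#' Value of the empty coalition
#'
#' The no-information convention per metric: PR-AUC of a constant
#' predictor equals the test prevalence (its random-guessing baseline);
#' ROC-AUC of a constant predictor is 0.5; R-squared, Efron
#' pseudo-R-squared and the IMV of the prevalence baseline against itself
#' are 0.
#'
#' @param y_test binary test outcomes (only the prevalence is used).
#' @param metric_name one of `"pr_auc"`, `"roc_auc"`, `"r2"`,
#'   `"pseudo_r2"`, `"imv"`.
#' @return The baseline metric value.
#' @export
empty_coalition_value <- function(y_test, metric_name) {
  switch(metric_name,
         pr_auc = mean(y_test),
         roc_auc = 0.5,
         r2 = 0,
         pseudo_r2 = 0,
         imv = 0,
         stop("unsupported metric: ", metric_name, call. = FALSE))
}

#' Evaluate (with caching) the value of one domain coalition
#'
#' Fits `model_spec` on exactly the features the domain map assigns to
#' the coalition's domains, using training rows only, and returns the
#' requested metric on the test rows. Results are cached in the ledger
#' under the coalition key (and the model seed), so a second call with
#' the same key performs no refit.
#'
#' @param members character vector of domain names (non-empty).
#' @param train,test `cohort_table`s from one split.
#' @param map a `domain_map`.
#' @param spec a [model_spec()] (the gradient-boosted tree model by
#'   default in [run_domain_analysis()]).
#' @param ledger a [coalition_ledger()].
#' @return The cached or freshly computed metric value.
#' @export
coalition_value <- function(members, train, test, map, spec, ledger) {
  if (length(members) == 0L) {
    stop("coalition must be non-empty; use empty_coalition_value()",
         call. = FALSE)
  }
  key <- paste0(coalition_key(members), "@", spec$seed)
  hit <- ledger_get(ledger, key)
  if (!is.null(hit)) return(hit)
  feats <- domain_features(map, members)
  fit <- fit_model(spec, train, feats)
  p <- predict_proba(fit, test)
  y <- outcomes(test)
  v <- switch(ledger$metric_name,
              pr_auc = pr_auc(y, p),
              roc_auc = roc_auc(y, p),
              r2 = r2_binary(y, p),
              pseudo_r2 = pseudo_r2(y, p),
              imv = imv(y, prevalence_baseline(y), p),
              stop("unsupported metric: ", ledger$metric_name,
                   call. = FALSE))
  ledger_set(ledger, key, v)
  v
}

#' Domain importances from a complete coalition ledger
#'
#' For each domain d, the marginal contributions
#' `m(S) = v(S + d) - v(S)` are collected over all 2^(D-1) coalitions S
#' not containing d (including the empty coalition, whose value is the
#' metric's no-information baseline). `weighting = "unweighted_mean"`
#' averages them all equally — the headline definition of the analysis;
#' `weighting = "shapley"` applies the Shapley coefficients
#' `|S|! (D-|S|-1)! / D!`, under which the importances sum exactly to
#' `v(full) - v(empty)`.
#'
#' @param ledger a `coalition_ledger` holding every coalition of
#'   `domains` under `key_suffix` (plus an `"<empty>"` entry or
#'   `empty_value`).
#' @param domains character vector of domain names.
#' @param weighting `"unweighted_mean"` (default) or `"shapley"`.
#' @param empty_value v(empty); defaults to the ledger's `"<empty>"`
#'   entry.
#' @param key_suffix seed suffix used when the ledger was filled by
#'   [coalition_value()] (e.g. `"@11"`); empty for hand-built ledgers.
#' @return A `domain_importance` data.frame: `domain`, `importance`,
#'   `se` (across that domain's marginals), `n_marginals`, `weighting`.
#' @export
domain_importance <- function(ledger, domains,
                              weighting = c("unweighted_mean", "shapley"),
                              empty_value = NULL, key_suffix = "") {
  weighting <- match.arg(weighting)
  D <- length(domains)
  lookup <- function(members) {
    if (length(members) == 0L) {
      if (!is.null(empty_value)) return(empty_value)
      v <- ledger_get(ledger, paste0("<empty>", key_suffix))
      if (is.null(v)) stop("ledger lacks the empty-coalition value",
                           call. = FALSE)
      return(v)
    }
    v <- ledger_get(ledger, paste0(coalition_key(members), key_suffix))
    if (is.null(v)) stop("incomplete ledger: missing coalition ",
                         coalition_key(members), call. = FALSE)
    v
  }
  rows <- lapply(sort(domains), function(d) {
    others <- setdiff(domains, d)
    subsets <- c(list(character(0)),
                 if (length(others) > 0) {
                   unlist(lapply(seq_along(others), function(k)
                     utils::combn(sort(others), k, simplify = FALSE)),
                     recursive = FALSE)
                 })
    marg <- vapply(subsets, function(S) lookup(c(S, d)) - lookup(S),
                   numeric(1))
    wts <- if (weighting == "shapley") {
      s <- lengths(subsets)
      factorial(s) * factorial(D - s - 1) / factorial(D)
    } else rep(1 / length(marg), length(marg))
    data.frame(domain = d,
               importance = sum(wts * marg),
               se = if (length(marg) > 1L)
                 stats::sd(marg) / sqrt(length(marg)) else 0,
               n_marginals = length(marg),
               weighting = weighting,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("domain_importance", "data.frame"))
}

#' Run the full leave-one-domain-out analysis
#'
#' Per seed: split the cohort (the same split serves every coalition, so
#' marginals always compare models on identical test rows), evaluate all
#' 2^D - 1 coalitions plus the empty baseline, and compute per-domain
#' importances; final importances are the across-seed mean with its
#' standard error.
#'
#' @param cohort a `cohort_table`.
#' @param map a `domain_map` (at most 12 domains).
#' @param spec coalition model (default: leaf-wise gradient-boosted
#'   trees).
#' @param split split parameters; the seed field is replaced per
#'   replication.
#' @param seeds integer vector of replication seeds.
#' @param metric_name evaluation metric (default `"pr_auc"`).
#' @param weighting marginal weighting (see [domain_importance()]).
#' @return List with `importance` (data.frame: domain, mean importance
#'   across seeds, SE across seeds, per-seed rank of that domain),
#'   `per_seed` (per-seed `domain_importance` tables), `ranking`
#'   (domains by decreasing mean importance) and `ledger`.
#' @export
run_domain_analysis <- function(cohort, map,
                                spec = model_spec("gbm_leafwise"),
                                split = split_spec(), seeds = 1:10,
                                metric_name = "pr_auc",
                                weighting = "unweighted_mean") {
  validate_domain_map(cohort, map)
  domains <- map$domains
  coalitions <- enumerate_coalitions(domains)
  ledger <- coalition_ledger(metric_name)
  per_seed <- list()
  for (sd in seeds) {
    split$seed <- as.integer(sd)
    parts <- split_cohort(cohort, split)
    sp <- spec
    sp$seed <- child_seed(sd, "coalition_fit")
    suffix <- paste0("@", sp$seed)
    ledger_set(ledger, paste0("<empty>", suffix),
               empty_coalition_value(outcomes(parts$test), metric_name))
    for (S in coalitions) {
      coalition_value(S, parts$train, parts$test, map, sp, ledger)
    }
    per_seed[[as.character(sd)]] <-
      domain_importance(ledger, domains, weighting = weighting,
                        key_suffix = suffix)
  }
  imp_mat <- vapply(per_seed, function(di) {
    stats::setNames(di$importance, di$domain)[sort(domains)]
  }, numeric(length(domains)))
  imp_mat <- matrix(imp_mat, nrow = length(domains),
                    dimnames = list(sort(domains), names(per_seed)))
  mean_imp <- rowMeans(imp_mat)
  se_imp <- if (ncol(imp_mat) > 1L) {
    apply(imp_mat, 1, stats::sd) / sqrt(ncol(imp_mat))
  } else rep(0, nrow(imp_mat))
  res <- data.frame(domain = rownames(imp_mat), importance = mean_imp,
                    se = se_imp, n_seeds = ncol(imp_mat),
                    weighting = weighting, metric = metric_name,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$importance, res$domain), , drop = FALSE]
  rownames(res) <- NULL
  list(importance = res, per_seed = per_seed, ranking = res$domain,
       ledger = ledger)
}

#' Kendall rank correlation between two domain orderings
#'
#' @param ranking_a,ranking_b character vectors holding the same domain
#'   names in (possibly) different orders.
#' @return Kendall's tau in \[-1, 1\].
#' @export
ranking_tau <- function(ranking_a, ranking_b) {
  stopifnot(setequal(ranking_a, ranking_b))
  ra <- match(sort(ranking_a), ranking_a)
  rb <- match(sort(ranking_a), ranking_b)
  unname(stats::cor(ra, rb, method = "kendall"))
}
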