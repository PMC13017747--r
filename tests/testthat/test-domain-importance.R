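test_that("coalition enumeration counts 2^D - 1 subsets in stable order", {
  for (D in 1:10) {
    doms <- paste0("d", seq_len(D))
    expect_length(enumerate_coalitions(doms), 2^D - 1)
  }
  # D = 3 verified by explicit listing
  got <- enumerate_coalitions(c("b", "a", "c"))
  expect_equal(got, list("a", "b", "c", c("a", "b"), c("a", "c"),
                         c("b", "c"), c("a", "b", "c")))
  expect_error(enumerate_coalitions(paste0("d", 1:13)), "12 domains")
})

test_that("empty-coalition values follow the per-metric baselines", {
  y <- rep(c(1, 0), c(316, 684))
  expect_equal(empty_coalition_value(y, "pr_auc"), 0.316)
  expect_equal(empty_coalition_value(y, "roc_auc"), 0.5)
  expect_equal(empty_coalition_value(y, "r2"), 0)
  expect_equal(empty_coalition_value(y, "imv"), 0)
  expect_error(empty_coalition_value(y, "brier"), "unsupported")
})

test_that("domain importances match a brute-force oracle on random ledgers", {
  doms <- c("a", "b", "c")
  for (s in 1:20) {
    vals <- random_ledger(doms, s)
    led <- as_coalition_ledger(vals)
    for (wt in c("unweighted_mean", "shapley")) {
      di <- domain_importance(led, doms, weighting = wt)
      oracle <- brute_force_importance(as.list(vals), doms, wt)
      expect_equal(setNames(di$importance, di$domain)[sort(doms)],
                   oracle[sort(doms)], tolerance = 1e-12)
    }
  }
})

test_that("additive value functions give importance = per-domain value under both weightings", {
  doms <- c("a", "b", "c", "d")
  cvals <- c(a = 0.12, b = 0.05, c = 0.2, d = 0.01)
  vals <- sapply(enumerate_coalitions(doms), function(S)
    sum(cvals[S]))
  names(vals) <- vapply(enumerate_coalitions(doms),
                        function(S) paste(sort(S), collapse = "+"),
                        character(1))
  vals["<empty>"] <- 0
  led <- as_coalition_ledger(vals)
  for (wt in c("unweighted_mean", "shapley")) {
    di <- domain_importance(led, doms, weighting = wt)
    expect_equal(setNames(di$importance, di$domain)[names(cvals)],
                 cvals, tolerance = 1e-12)
  }
})

test_that("Shapley weighting is efficient: importances sum to v(full) - v(empty)", {
  doms <- c("x", "y", "z")
  for (s in 1:5) {
    vals <- random_ledger(doms, 100 + s)
    di <- domain_importance(as_coalition_ledger(vals), doms,
                            weighting = "shapley")
    expect_lt(abs(sum(di$importance) -
                  (vals[["x+y+z"]] - vals[["<empty>"]])), 1e-10)
  }
})

test_that("incomplete ledgers are rejected with the missing coalition named", {
  vals <- random_ledger(c("a", "b"), 1)
  vals <- vals[names(vals) != "a+b"]
  expect_error(domain_importance(as_coalition_ledger(vals), c("a", "b")),
               "a\\+b")
})

test_that("coalition_value caches: repeated evaluation performs no refit", {
  gen <- small_synth(n = 300, seed = 4)
  parts <- split_cohort(gen$table, split_spec(seed = 1))
  led <- coalition_ledger("pr_auc")
  sp <- model_spec("gbm_leafwise", seed = 5)
  fit_count(reset = TRUE)
  v1 <- coalition_value(c("socioeconomic"), parts$train, parts$test,
                        gen$map, sp, led)
  expect_equal(fit_count(), 1L)
  v2 <- coalition_value(c("socioeconomic"), parts$train, parts$test,
                        gen$map, sp, led)
  expect_equal(fit_count(), 1L)
  expect_identical(v1, v2)
  expect_error(coalition_value(character(0), parts$train, parts$test,
                               gen$map, sp, led), "non-empty")
})

test_that("ledger JSON round-trips", {
  vals <- random_ledger(c("a", "b"), 3)
  led <- as_coalition_ledger(vals, metric_name = "roc_auc")
  path <- tempfile(fileext = ".json")
  write_ledger(led, path)
  led2 <- read_ledger(path)
  expect_equal(ledger_values(led2), ledger_values(led))
  expect_equal(led2$metric_name, "roc_auc")
})

test_that("full-coalition value is consistent with a direct fit", {
  gen <- small_synth(n = 400, seed = 17)
  res <- run_domain_analysis(gen$table, gen$map, seeds = 2)
  suffix <- paste0("@", mortdomains:::child_seed(2, "coalition_fit"))
  full_key <- paste0(paste(sort(gen$map$domains), collapse = "+"), suffix)
  v_full <- ledger_values(res$ledger)[[full_key]]
  parts <- split_cohort(gen$table, split_spec(seed = 2))
  sp <- model_spec("gbm_leafwise",
                   seed = mortdomains:::child_seed(2, "coalition_fit"))
  fit <- fit_model(sp, parts$train)
  expect_equal(v_full, pr_auc(outcomes(parts$test),
                              predict_proba(fit, parts$test)),
               tolerance = 1e-12)
  # ledger holds all 2^D entries (including the empty baseline)
  expect_length(ledger_values(res$ledger), 2^3)
  # per-domain marginal count is 2^(D-1)
  expect_true(all(res$per_seed[["2"]]$n_marginals == 4L))
})

test_that("domain ranking recovers a strongly planted ordering (small cohort)", {
  spec <- cohort_spec(n = 1200,
                      domain_sizes = c(demography = 2, strong = 3, weak = 3),
                      domain_betas = list(demography = numeric(0),
                                          strong = rep(0.9, 3),
                                          weak = rep(0.05, 3)),
                      age_beta_linear = 0.1, gender_beta = 0,
                      target_prevalence = 0.3, missing_rate = 0, seed = 23)
  gen <- generate_cohort(spec)
  res <- run_domain_analysis(gen$table, gen$map, seeds = 1:2)
  expect_equal(res$ranking[1], "strong")
  expect_equal(ranking_tau(res$ranking, res$ranking), 1)
  expect_equal(ranking_tau(c("a", "b", "c"), c("c", "b", "a")), -1)
})
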