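test_that("roc_auc matches pairwise enumeration and handles ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1), c(0.5, 0.5)), 0.5)
  # brute-force oracle: fraction of positive-negative pairs won (ties 1/2)
  pairwise_auc <- function(y, p) {
    pos <- p[y == 1]; neg <- p[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.2, 0.8, 0.1)),
               pairwise_auc(c(0, 0, 1, 1), c(0.9, 0.2, 0.8, 0.1)))
  for (s in 1:10) {
    y <- with_test_seed(s, rbinom(40, 1, 0.3))
    p <- with_test_seed(s + 100, round(runif(40), 1))  # force ties
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(y, p), pairwise_auc(y, p), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both outcome classes")
})

test_that("roc_auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  y <- with_test_seed(5, rbinom(200, 1, 0.3))
  p <- with_test_seed(6, runif(200))
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, p), ref, tolerance = 1e-10)
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  y <- with_test_seed(1, rbinom(100, 1, 0.4))
  p <- with_test_seed(2, runif(100))
  a <- roc_auc(y, p)
  expect_equal(roc_auc(y, plogis(5 * p - 2)), a, tolerance = 1e-12)
  expect_equal(roc_auc(y, p^3), a, tolerance = 1e-12)
})

test_that("pr_auc is average precision with the prevalence baseline", {
  expect_equal(pr_auc(c(0, 1, 1), c(0.1, 0.8, 0.9)), 1.0)
  # hand-enumerated PR curve: thresholds .9, .8, .7, .6 give
  # (R, P) = (1/2, 1), (1/2, 1/2), (1, 2/3), (1, 1/2) -> AP = 5/6
  expect_equal(pr_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 5 / 6,
               tolerance = 1e-12)
  # constant predictor scores exactly the prevalence
  for (prev in c(0.1, 0.25, 0.5)) {
    y <- rep(c(1, 0), round(c(prev, 1 - prev) * 40))
    expect_equal(pr_auc(y, rep(0.42, length(y))), mean(y),
                 tolerance = 1e-12)
  }
  expect_error(pr_auc(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("Efron pseudo-R2 and binary R2 coincide to machine precision", {
  expect_equal(r2_binary(c(0, 1, 1), c(0.2, 0.6, 0.9)),
               1 - (0.04 + 0.16 + 0.01) / (2 / 3), tolerance = 1e-12)
  y <- c(0, 1, 1, 0, 1)
  expect_equal(r2_binary(y, rep(mean(y), 5)), 0, tolerance = 1e-12)
  expect_equal(r2_binary(y, y), 1, tolerance = 1e-12)
  for (s in 1:10) {
    y <- with_test_seed(s, rbinom(50, 1, 0.4))
    p <- with_test_seed(s + 50, runif(50))
    if (length(unique(y)) < 2) next
    expect_lt(abs(r2_binary(y, p) - pseudo_r2(y, p)), 1e-12)
  }
  expect_error(r2_binary(c(1, 1, 1), c(0.2, 0.3, 0.4)), "constant")
})

test_that("entropy-equivalent w inverts the Bernoulli entropy", {
  expect_equal(entropy_equivalent_w(log(0.5)), 0.5, tolerance = 1e-9)
  expect_equal(entropy_equivalent_w(0.9 * log(0.9) + 0.1 * log(0.1)), 0.9,
               tolerance = 1e-9)
  # grid-search oracle for an arbitrary log-likelihood
  grid <- seq(0.5, 1 - 1e-9, length.out = 2e6)
  ent <- grid * log(grid) + (1 - grid) * log(1 - grid)
  w_grid <- grid[which.min(abs(ent - (-0.5)))]
  expect_equal(entropy_equivalent_w(-0.5), w_grid, tolerance = 1e-5)
  # round trip across the admissible range
  for (w in seq(0.5, 1 - 1e-6, length.out = 25)) {
    ll <- w * log(w) + (1 - w) * log(1 - w)
    expect_lt(abs(entropy_equivalent_w(ll) - w), 1e-9)
  }
  # worse than a coin flip clips to 0.5
  expect_equal(entropy_equivalent_w(-2), 0.5, tolerance = 1e-9)
  expect_error(entropy_equivalent_w(0.1), "negative")
})

test_that("IMV is zero on self-comparison and monotone in fit quality", {
  y <- c(0, 1, 1, 0)
  p <- c(0.3, 0.7, 0.6, 0.2)
  expect_equal(imv(y, p, p), 0, tolerance = 1e-9)
  # grid-search oracle on a small worked case
  p0 <- rep(mean(y), 4)
  p1 <- c(0.2, 0.8, 0.7, 0.1)
  ww <- function(ll) {
    grid <- seq(0.5, 1 - 1e-9, length.out = 2e6)
    ent <- grid * log(grid) + (1 - grid) * log(1 - grid)
    grid[which.min(abs(ent - ll))]
  }
  ll0 <- mean(y * log(p0) + (1 - y) * log(1 - p0))
  ll1 <- mean(y * log(p1) + (1 - y) * log(1 - p1))
  expect_equal(imv(y, p0, p1), (ww(ll1) - ww(ll0)) / ww(ll0),
               tolerance = 1e-4)
  expect_gt(imv(y, p0, p1), 0)
  # strictly increasing in enhanced log-likelihood, baseline fixed
  p_seq <- lapply(c(0.55, 0.65, 0.75), function(q) ifelse(y == 1, q, 1 - q))
  imvs <- vapply(p_seq, function(p1) imv(y, p0, p1), numeric(1))
  expect_true(all(diff(imvs) > 0))
})

test_that("aggregate_report computes means, standard errors and IP", {
  per_seed <- data.frame(model = "m1", metric = "pr_auc", seed = 1:3,
                         value = c(0.1, 0.2, 0.3))
  rep1 <- aggregate_report(per_seed, in_sample_prevalence = c(0.3, 0.31, 0.29))
  expect_equal(rep1$mean, 0.2)
  expect_equal(rep1$se, sd(c(0.1, 0.2, 0.3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(attr(rep1, "in_sample_prevalence"), 0.3)
  # single seed: SE reported as 0
  rep2 <- aggregate_report(data.frame(model = "m", metric = "x", seed = 1,
                                      value = 0.5))
  expect_equal(rep2$se, 0)
  # shape: 3 models x 2 metrics x 10 seeds -> 6 rows
  grid <- expand.grid(model = paste0("m", 1:3), metric = c("a", "b"),
                      seed = 1:10, stringsAsFactors = FALSE)
  grid$value <- with_test_seed(1, runif(nrow(grid)))
  expect_equal(nrow(aggregate_report(grid)), 6L)
})
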