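# Shared fixture builders (all data generated in code).

# Minimal hand-written cohort: 5 rows, 4 features (age, female + 2) in
# 2 domains.
tiny_cohort <- function() {
  df <- data.frame(
    id = paste0("p", 1:5),
    death = c(0, 1, 0, 1, 0),
    age = c(55, 80, 62, 91, 70),
    female = c(1, 0, 1, 1, 0),
    income = c(1.2, -0.5, 0.3, NA, 0.8),
    wealth = c(0.4, -1.1, NA, -0.2, 1.5))
  tbl <- cohort_table(df)
  map <- domain_map(c(age = "demography", female = "demography",
                      income = "socioeconomic", wealth = "socioeconomic"))
  list(table = tbl, map = map)
}

# Moderate synthetic cohort for model-level tests.
small_synth <- function(n = 600, seed = 42, missing_rate = 0,
                        strength = 1.5) {
  spec <- cohort_spec(
    n = n,
    domain_sizes = c(demography = 2, socioeconomic = 4, psychology = 3),
    domain_betas = list(
      demography = numeric(0),
      socioeconomic = domain_betas_for_contribution(4, 0.3, strength),
      psychology = rep(0, 3)),
    within_domain_rho = 0.3, target_prevalence = 0.35,
    age_beta_linear = 1.2, female_fraction = 0.55, gender_beta = -0.4,
    missing_rate = missing_rate, seed = seed)
  generate_cohort(spec)
}

# Random coalition-value ledgers over given domains (for oracle tests).
random_ledger <- function(domains, seed) {
  keys <- vapply(enumerate_coalitions(domains),
                 function(S) paste(sort(S), collapse = "+"), character(1))
  vals <- with_test_seed(seed, stats::runif(length(keys)))
  v <- stats::setNames(vals, keys)
  v["<empty>"] <- with_test_seed(seed + 1000, stats::runif(1))
  v
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent brute-force domain-importance computation: direct loops
# over all subsets, no shared code with the package implementation.
brute_force_importance <- function(values, domains, weighting) {
  D <- length(domains)
  get_v <- function(S) {
    key <- if (length(S) == 0) "<empty>" else paste(sort(S), collapse = "+")
    unname(values[[key]])
  }
  all_subsets <- function(xs) {
    out <- list(character(0))
    for (x in xs) out <- c(out, lapply(out, function(s) c(s, x)))
    out
  }
  sapply(sort(domains), function(d) {
    subs <- all_subsets(setdiff(domains, d))
    marg <- vapply(subs, function(S) get_v(c(S, d)) - get_v(S), numeric(1))
    if (weighting == "shapley") {
      s <- lengths(subs)
      sum(factorial(s) * factorial(D - s - 1) / factorial(D) * marg)
    } else {
      mean(marg)
    }
  })
}
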