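# Internal helpers.

# Run `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no global seed mutation leaks.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stage label, keeping the result
# a valid 32-bit integer. Deterministic and stage-separated so e.g. the
# split and the model fit never share a stream.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a
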