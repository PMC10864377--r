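# Internal helpers: link functions, scoped RNG, substream seeds.

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds: one root seed fans out to n child seeds so
# any replicate/colony/cell can be re-run in isolation. Seeds stay < 2^31.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

stop_contract <- function(...) stop(..., call. = FALSE)
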