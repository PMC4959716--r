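# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched. All stochastic package operations funnel through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a child seed from a base seed and an index, staying inside 32-bit
# signed range. Deterministic and collision-poor for desk-scale cohorts.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# Half-up rounding to `digits` decimals (R's round() ties to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
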