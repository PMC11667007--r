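#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: FNV-style string hash folded into the
# 31-bit positive integer range, so every source of randomness in a run can
# be traced back to (master seed, purpose string).
derive_seed <- function(master, purpose) {
  stopifnot(is.numeric(master), length(master) == 1L)
  s <- paste0(format(as.integer(master)), "/", purpose)
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- (bitwXor(h, b) * 16777619) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-away-from-zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
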