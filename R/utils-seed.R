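#' @keywords internal
"_PACKAGE"

# Modulus for derived seeds: largest prime below 2^31, keeps every derived
# seed a valid 32-bit integer.
.SEED_MOD <- 2147483647

#' Derive a reproducible substream seed
#'
#' Stable integer hash of a master seed and a stream index (Lehmer-style
#' multiplicative mixing). Used so that every animal, split and model fit
#' draws from its own reproducible stream: regenerating part of a cohort
#' never perturbs the rest.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer stream index (vectorised).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  s <- (abs(as.numeric(master_seed)) %% .SEED_MOD)
  # two rounds of multiplicative mixing; operands stay < 2^53 so the
  # double-precision arithmetic is exact
  h <- (s * 48271) %% .SEED_MOD
  h <- (h + (as.numeric(index) + 1) * 69621) %% .SEED_MOD
  h <- (h * 16807) %% .SEED_MOD
  as.integer(h %% (.SEED_MOD - 1) + 1)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards (no hidden global state).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
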