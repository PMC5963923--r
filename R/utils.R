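# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Map angles (degrees) to the axial range [0, 180).
normalize_axial <- function(theta) {
  out <- theta %% 180
  # -1e-14 %% 180 can return 180 exactly under floating point
  out[out >= 180] <- 0
  out
}

# Acute axial difference between two orientations, in [0, 90].
axial_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.  All generator determinism
# flows through this single gate.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
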