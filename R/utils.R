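# Internal helpers: seeding, truncated draws, small numerics.

# Stable 32-bit hash so per-subject random streams are reproducible across
# platforms and independent of evaluation order.
stable_hash <- function(seed, id) {
  bytes <- utf8ToInt(as.character(id))
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, ...) {
  stable_hash(seed, paste(..., sep = "/"))
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Truncated-normal draws by inverse-CDF so a scale of zero degenerates to the
# location and truncation keeps values physical without rejection loops.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Interquartile range of a normal spans 2 * qnorm(0.75) = 1.349 standard
# deviations; used to convert printed Q1-Q3 summaries into a scale.
iqr_to_sd <- function(q1, q3) (q3 - q1) / (2 * stats::qnorm(0.75))

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
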