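# Shared constants and small internal helpers.

#' Unit-conversion and numerical constants
#'
#' `PA_PER_MMHG` is the exact-to-six-digits conversion 1 mmHg = 133.322 Pa.
#' `TENSION_COEF` converts radius (um) times pressure (mmHg) to lateral
#' tension in mN/m through Laplace's law T = R * dp / 2:
#' T\[mN/m\] = R\[um\] * |dp|\[mmHg\] * 133.322e-6 * 1e3 / 2.
#' `FLAT_CURVATURE_TOL` (1/um) is the magnitude below which a fitted
#' curvature is reported as exactly flat (radius infinite) to avoid
#' numerical blow-up in Laplace conversion and inverse-radius binning.
#'
#' @name patchtension-constants
#' @keywords internal
NULL

PA_PER_MMHG <- 133.322
TENSION_COEF <- PA_PER_MMHG * 1e-6 * 1e3 / 2  # = 0.066661 mN/m per (um * mmHg)
FLAT_CURVATURE_TOL <- 1e-3

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded simulation helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation so that per-cell / per-sweep streams are
# reproducible independently of iteration order.  All arithmetic stays well
# below 2^53 so the double-precision modular reduction is exact; the result
# is always a positive integer below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  m <- 2147483563
  h <- 11
  for (x in parts) {
    h <- (h * 69069 + (as.numeric(x) %% m) + 1) %% m
  }
  as.integer(h + 1)
}

# Small rolling hash (not cryptographic) used for config hashes and output
# checksums in run reports.
content_hash <- function(x) {
  if (is.character(x)) x <- utf8ToInt(paste(x, collapse = "\n"))
  if (is.raw(x)) x <- as.integer(x)
  m <- 2^31 - 1
  h <- 7
  for (b in x) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

file_hash <- function(path) {
  content_hash(readBin(path, "raw", n = file.info(path)$size))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Centered rolling mean with window truncated at the ends (partial windows
# averaged over the available samples), matching the line-scan smoothing.
rolling_mean <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
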