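# Statistical pipeline: Boltzmann activation fits, plateau normalization,
# pooling and binning, SD-weighted tension fits, and exponential recovery
# fits.  This reproduces, step by step, the standard analysis for pooled
# pressure-clamp dose-response data:
#   * per-cell current-pressure curves fit with I = Imax / (1 + exp(-(P - P50)/k))
#   * responses normalized to the per-cell fitted plateau (or patch maximum)
#   * normalized responses pooled, binned (1 mN/m tension bins), and the
#     binned means fit with a Boltzmann in tension, weighted by per-bin SD
#   * recovery from inactivation fit with I(t) = Imax - A * exp(-(t - t0)/tau).

#' Boltzmann activation curve
#'
#' @param x stimulus values (tension in mN/m or pressure magnitude in mmHg).
#' @param i_max plateau (maximal) response.
#' @param x50 stimulus of half-maximal activation (T50 or P50).
#' @param k slope factor, same units as `x`; must be positive for an
#'   activation curve that increases with stimulus.
#' @return response values `i_max / (1 + exp(-(x - x50)/k))`.
#' @export
#' @examples
#' boltzmann(2.7, i_max = 0.99, x50 = 2.7, k = 0.8)  # exactly half of i_max
boltzmann <- function(x, i_max, x50, k) {
  i_max / (1 + exp(-(x - x50) / k))
}

#' Fit a Boltzmann activation curve by (weighted) nonlinear least squares
#'
#' Fits `y = i_max / (1 + exp(-(x - x50)/k))`.  Initialization follows the
#' conventional recipe: `i_max` from the maximal response, `x50` from linear
#' interpolation of the half-maximal crossing, `k` from a tenth of the
#' stimulus range.  When per-point (or per-bin) standard deviations are
#' supplied the fit minimizes `sum((y - f)^2 / sd^2)`, i.e. each point is
#' weighted by the inverse variance of its bin, which is how pooled binned
#' dose-response data are conventionally weighted.
#'
#' @param x stimulus values.
#' @param y responses (peak currents, pA or normalized).
#' @param sd optional per-point standard deviations used as weights
#'   (weight = 1/sd^2).  Non-positive or non-finite SDs are replaced by the
#'   median of the positive SDs.
#' @param domain `"tension"` or `"pressure"`; recorded on the result so
#'   that tension-domain midpoints (mN/m) are never silently mixed with
#'   pressure-domain midpoints (mmHg).
#' @param units stimulus units label (defaults to mN/m for tension, mmHg
#'   for pressure).
#' @return an object of class `boltzmann_fit` with elements `i_max`, `x50`,
#'   `k`, standard errors `se_i_max`, `se_x50`, `se_k`, `cov`, `n`,
#'   `weighted`, `domain`, `units`, `fitted`, `rss`, `converged`.
#' @export
fit_boltzmann <- function(x, y, sd = NULL, domain = c("tension", "pressure"),
                          units = NULL) {
  domain <- match.arg(domain)
  units <- units %||% switch(domain, tension = "mN/m", pressure = "mmHg")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(sd)) sd <- sd[ok]
  n <- length(y)
  if (n < 4L) stop("fit_boltzmann: need at least 4 points")
  if (diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    stop("fit_boltzmann: degenerate data (all responses equal)")
  }
  w <- NULL
  if (!is.null(sd)) {
    s <- sd
    bad <- !is.finite(s) | s <= 0
    if (all(bad)) stop("fit_boltzmann: all supplied SDs are non-positive")
    s[bad] <- stats::median(s[!bad])
    w <- 1 / s^2
  }
  # Initialization
  i0 <- max(y)
  half <- i0 / 2
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  above <- which(ys >= half)
  x50_0 <- if (length(above) == 0L) stats::median(xs) else {
    j <- above[1L]
    if (j == 1L) xs[1L] else {
      xs[j - 1L] + (half - ys[j - 1L]) / (ys[j] - ys[j - 1L]) * (xs[j] - xs[j - 1L])
    }
  }
  k0 <- max(diff(range(x)) / 10, 1e-3)
  if (!any(x < x50_0) || !any(x > x50_0)) {
    warning("fit_boltzmann: points do not span the apparent midpoint; fit may be poorly constrained")
  }
  fn <- function(p) boltzmann(x, p[1], p[2], p[3])
  jac <- function(p) {
    e <- exp(-(x - p[2]) / p[3])
    den <- (1 + e)^2
    cbind(1 / (1 + e),
          -p[1] * e / (p[3] * den),
          -p[1] * e * (x - p[2]) / (p[3]^2 * den))
  }
  lower <- c(1e-12, -Inf, 1e-9)
  upper <- c(2 * max(y), Inf, Inf)
  fit <- lm_fit(fn, jac, start = c(i0, x50_0, k0), y = y, weights = w,
                lower = lower, upper = upper)
  if (!fit$converged) {
    # grid multi-start over (x50, k); i_max is conditionally linear given
    # the logistic shape, so it is profiled out at each grid node
    ww <- if (is.null(w)) rep(1, n) else w
    span <- diff(range(x))
    grid <- expand.grid(
      x50 = seq(min(x) - 0.25 * span, max(x) + 0.75 * span, length.out = 31),
      k = exp(seq(log(span / 50), log(span), length.out = 15)))
    best <- fit
    for (g in seq_len(nrow(grid))) {
      b <- 1 / (1 + exp(-(x - grid$x50[g]) / grid$k[g]))
      im <- sum(ww * b * y) / max(sum(ww * b^2), 1e-300)
      im <- min(max(im, lower[1]), upper[1])
      cand <- lm_fit(fn, jac, start = c(im, grid$x50[g], grid$k[g]), y = y,
                     weights = w, lower = lower, upper = upper, maxit = 100)
      if (cand$ss < best$ss) best <- cand
    }
    fit <- best
  }
  if (!fit$converged && fit$ss > 1e-10 * sum(y^2)) {
    stop(sprintf(
      "fit_boltzmann: did not converge (iter=%d, rss=%.4g, start=[%.3g, %.3g, %.3g])",
      fit$iter, fit$ss, i0, x50_0, k0))
  }
  structure(list(
    i_max = fit$par[1], x50 = fit$par[2], k = fit$par[3],
    se_i_max = fit$se[1], se_x50 = fit$se[2], se_k = fit$se[3],
    cov = fit$cov, n = n, weighted = !is.null(w),
    domain = domain, units = units,
    fitted = fit$fitted, rss = fit$ss, converged = fit$converged),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit (%s domain, %d points%s)\n", x$domain, x$n,
              if (x$weighted) ", SD-weighted" else ""))
  cat(sprintf("  I_max = %.4g +/- %.2g\n", x$i_max, x$se_i_max))
  cat(sprintf("  X50   = %.4g +/- %.2g %s\n", x$x50, x$se_x50, x$units))
  cat(sprintf("  k     = %.4g +/- %.2g %s\n", x$k, x$se_k, x$units))
  invisible(x)
}

#' Fit one cell's current-pressure relation
#'
#' Per-cell pressure fits are performed on the pressure magnitude so that
#' negative-pressure (suction) series yield a positive midpoint internally;
#' the reported `p50` carries the sign of the applied pressures.  Per-cell
#' fits are unweighted (no per-point SDs exist at this stage).
#'
#' @param dp_mmhg signed applied pressures (mmHg).
#' @param peak_pa peak currents (pA, magnitudes).
#' @return a `boltzmann_fit` with an extra element `p50_signed`.
#' @export
fit_cell_pressure <- function(dp_mmhg, peak_pa) {
  sgn <- if (sum(dp_mmhg < 0) >= sum(dp_mmhg > 0)) -1 else 1
  fit <- fit_boltzmann(abs(dp_mmhg), peak_pa, domain = "pressure")
  fit$p50_signed <- sgn * fit$x50
  fit
}

#' Normalize responses per cell
#'
#' @param responses data.frame with at least `cell_id`, `dp_mmhg`,
#'   `peak_pa` columns.
#' @param mode `"plateau_of_fit"`: divide by the per-cell fitted Boltzmann
#'   plateau from the current-pressure fit; `"max_response"`: divide by the
#'   per-cell maximal response.
#' @return the input with an added `norm_current` column; cells whose
#'   plateau fit fails are dropped with a warning.  Attributes:
#'   `norm_mode`, and for plateau mode `cell_fits` (list of per-cell fits).
#' @export
normalize_responses <- function(responses, mode = c("plateau_of_fit", "max_response")) {
  mode <- match.arg(mode)
  stopifnot(all(c("cell_id", "dp_mmhg", "peak_pa") %in% names(responses)))
  cells <- split(responses, responses$cell_id)
  fits <- list()
  out <- lapply(names(cells), function(id) {
    d <- cells[[id]]
    if (mode == "max_response") {
      d$norm_current <- d$peak_pa / max(d$peak_pa)
      return(d)
    }
    fit <- tryCatch(fit_cell_pressure(d$dp_mmhg, d$peak_pa), error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("normalize_responses: cell %s excluded (plateau fit failed: %s)",
                      id, conditionMessage(fit)))
      return(NULL)
    }
    fits[[id]] <<- fit
    d$norm_current <- d$peak_pa / fit$i_max
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "norm_mode") <- mode
  if (mode == "plateau_of_fit") attr(res, "cell_fits") <- fits
  res
}

#' Pool normalized responses and bin by stimulus
#'
#' Bins are left-closed, right-open, anchored at zero, of constant width
#' (1 mN/m for tension, 0.05 um^-1 for inverse radius by convention).
#' Empty bins are dropped; singleton bins are retained with their SD
#' replaced by the median SD of the multi-member bins so that every
#' retained bin can participate in SD-weighted fitting.
#'
#' @param x stimulus values (tension mN/m or inverse radius 1/um).
#' @param y normalized responses.
#' @param bin_width bin width in stimulus units.
#' @param stimulus label, `"tension"` or `"inverse_radius"`.
#' @return data.frame of class `binned_histogram` with columns `bin_lo`,
#'   `bin_hi`, `center`, `mean`, `sd`, `sem`, `n`.
#' @export
pool_and_bin <- function(x, y, bin_width = 1,
                         stimulus = c("tension", "inverse_radius")) {
  stimulus <- match.arg(stimulus)
  stopifnot_scalar_pos(bin_width, "bin_width")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 1L) stop("pool_and_bin: no finite responses")
  idx <- floor(x / bin_width)
  agg <- lapply(split(y, idx), function(v) {
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_, n = length(v))
  })
  ids <- as.numeric(names(agg))
  m <- do.call(rbind, agg)
  med_sd <- stats::median(m[, "sd"], na.rm = TRUE)
  if (!is.finite(med_sd)) med_sd <- max(stats::sd(y), 1e-6)
  sd_out <- ifelse(is.na(m[, "sd"]), med_sd, m[, "sd"])
  out <- data.frame(
    bin_lo = ids * bin_width,
    bin_hi = (ids + 1) * bin_width,
    center = (ids + 0.5) * bin_width,
    mean = m[, "mean"], sd = sd_out, sem = sd_out / sqrt(m[, "n"]),
    n = as.integer(m[, "n"]))
  out <- out[order(out$center), ]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  attr(out, "stimulus") <- stimulus
  class(out) <- c("binned_histogram", "data.frame")
  out
}

#' Fit the pooled, binned tension-response histogram
#'
#' Fits a Boltzmann to bin centers vs. per-bin mean normalized current,
#' weighted by the per-bin standard deviation of the normalized amplitude.
#'
#' @param hist a `binned_histogram` from [pool_and_bin()].
#' @param weighted use per-bin SD weights (default TRUE).
#' @return a `boltzmann_fit` in the tension domain.
#' @export
fit_tension_curve <- function(hist, weighted = TRUE) {
  stopifnot(inherits(hist, "binned_histogram"))
  if (nrow(hist) < 4L) stop("fit_tension_curve: need at least 4 populated bins")
  fit_boltzmann(hist$center, hist$mean,
                sd = if (weighted) hist$sd else NULL,
                domain = "tension")
}

#' Fit recovery from inactivation versus prepulse duration
#'
#' Fits the saturating-exponential recovery model
#' `I(t) = i_max - A * exp(-(t - t0)/tau)` to normalized off-response peak
#' current as a function of prepulse duration `t`.  `t0` is fixed at the
#' shortest tested duration by default (freeing it is nearly degenerate
#' with `A` over a sparse duration grid); set `free_t0 = TRUE` to fit it.
#'
#' @param durations prepulse durations (s).
#' @param peaks normalized peak currents (same length, or a mean per
#'   distinct duration).
#' @param t0 reference time (s); default `min(durations)`.
#' @param free_t0 fit `t0` as a free parameter.
#' @return object of class `recovery_fit` with `i_max`, `A`, `t0`, `tau`
#'   and standard errors.
#' @export
fit_recovery <- function(durations, peaks, t0 = NULL, free_t0 = FALSE) {
  ok <- is.finite(durations) & is.finite(peaks)
  t <- durations[ok]; y <- peaks[ok]
  if (length(unique(t)) < 4L) stop("fit_recovery: need at least 4 distinct durations")
  if (stats::cor(t, y) < 0) {
    stop("fit_recovery: responses decrease with duration; expected a recovering (increasing) process")
  }
  t0 <- t0 %||% min(t)
  i0 <- max(y)
  a0 <- max(i0 - min(y), 1e-3)
  tau0 <- max(diff(range(t)) / 3, 1e-3)
  if (free_t0) {
    fn <- function(p) p[1] - p[2] * exp(-(t - p[4]) / p[3])
    jac <- function(p) {
      e <- exp(-(t - p[4]) / p[3])
      cbind(1, -e, -p[2] * e * (t - p[4]) / p[3]^2, -p[2] * e / p[3])
    }
    fit <- lm_fit(fn, jac, start = c(i0, a0, tau0, t0), y = y,
                  lower = c(-Inf, 1e-12, 1e-9, -Inf))
    par <- fit$par; se <- fit$se
    t0_hat <- par[4]; se_t0 <- se[4]
  } else {
    fn <- function(p) p[1] - p[2] * exp(-(t - t0) / p[3])
    jac <- function(p) {
      e <- exp(-(t - t0) / p[3])
      cbind(1, -e, -p[2] * e * (t - t0) / p[3]^2)
    }
    fit <- lm_fit(fn, jac, start = c(i0, a0, tau0), y = y,
                  lower = c(-Inf, 1e-12, 1e-9))
    par <- fit$par; se <- fit$se
    t0_hat <- t0; se_t0 <- 0
  }
  if (!fit$converged && fit$ss > 1e-10 * sum(y^2)) {
    stop("fit_recovery: did not converge")
  }
  structure(list(i_max = par[1], A = par[2], tau = par[3], t0 = t0_hat,
                 se_i_max = se[1], se_A = se[2], se_tau = se[3], se_t0 = se_t0,
                 n = length(y), rss = fit$ss, converged = fit$converged,
                 free_t0 = free_t0),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("Recovery fit: I(t) = I_max - A*exp(-(t - t0)/tau), n = %d\n", x$n))
  cat(sprintf("  I_max = %.4g +/- %.2g\n", x$i_max, x$se_i_max))
  cat(sprintf("  A     = %.4g +/- %.2g\n", x$A, x$se_A))
  cat(sprintf("  tau   = %.4g +/- %.2g s\n", x$tau, x$se_tau))
  cat(sprintf("  t0    = %.4g s%s\n", x$t0, if (x$free_t0) "" else " (fixed)"))
  invisible(x)
}

#' Percentile bootstrap confidence intervals for a tension-curve fit
#'
#' Resamples responses with replacement, re-runs binning and the weighted
#' Boltzmann fit, and returns percentile intervals for (i_max, x50, k).
#'
#' @param tension tensions (mN/m) of individual normalized responses.
#' @param norm_current normalized responses.
#' @param bin_width tension bin width (mN/m).
#' @param n_boot number of resamples.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return matrix with rows i_max, x50, k and columns lo, hi.
#' @export
boot_tension_ci <- function(tension, norm_current, bin_width = 1,
                            n_boot = 1000, level = 0.95, seed = 1) {
  n <- length(tension)
  with_seed(seed, {
    draws <- replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      f <- tryCatch({
        h <- pool_and_bin(tension[i], norm_current[i], bin_width)
        ft <- fit_tension_curve(h)
        c(ft$i_max, ft$x50, ft$k)
      }, error = function(e) c(NA_real_, NA_real_, NA_real_))
      f
    })
    a <- (1 - level) / 2
    ci <- t(apply(draws, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
    rownames(ci) <- c("i_max", "x50", "k")
    colnames(ci) <- c("lo", "hi")
    ci
  })
}
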