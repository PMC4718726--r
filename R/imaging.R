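# Membrane detection and circle fitting.
#
# The detector mirrors the classical line-scan procedure: scan lines run
# parallel to the pipette walls (i.e. along the pipette axis), the
# intensity along each line is smoothed with a centered 9-sample rolling
# mean, the global minimum localizes the membrane on that line, and the
# position is refined to subpixel precision by parabolic interpolation.
# The fitted circle radius is the membrane radius of curvature R.

#' Construct a patch image container
#'
#' @param intensities numeric matrix (rows = y, columns = x, origin
#'   top-left, 0-based pixel coordinates map to um via `pixel_size`).
#' @param pixel_size um per pixel.
#' @param wall_lines optional list of two lines (`list(point=, dir=)`, um
#'   coordinates); estimated from the image when absent.
#' @return object of class `patch_image`.
#' @export
patch_image <- function(intensities, pixel_size, wall_lines = NULL) {
  stopifnot(is.matrix(intensities), all(dim(intensities) > 0))
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 wall_lines = wall_lines, truth = NULL),
            class = "patch_image")
}

line_point_dist <- function(px, py, line) {
  # perpendicular distance of points to an infinite line
  nx <- -line$dir[2]; ny <- line$dir[1]
  abs((px - line$point[1]) * nx + (py - line$point[2]) * ny)
}

line_intersection <- function(l1, l2) {
  # solve p1 + a d1 = p2 + b d2
  A <- cbind(l1$dir, -l2$dir)
  if (abs(det(A)) < 1e-9) stop("wall lines are parallel")
  ab <- solve(A, l2$point - l1$point)
  l1$point + ab[1] * l1$dir
}

#' Estimate the two pipette wall lines from an image
#'
#' A weighted Hough transform over dark pixels finds the two dominant
#' straight ridges; each is then refined by a darkness-weighted total
#' least-squares line fit over its supporting pixels.
#'
#' @param image a `patch_image`.
#' @param theta_step Hough angular resolution, degrees.
#' @param min_rel_peak second peak must reach this fraction of the first.
#' @return list of two lines (`point`, `dir`, um coordinates), ordered so
#'   the first has the larger Hough weight; attribute `half_angle_deg`
#'   gives half the angle between them and `axis_angle_deg` the bisector
#'   direction.
#' @export
estimate_walls <- function(image, theta_step = 0.25, min_rel_peak = 0.30) {
  I <- image$intensities
  ps <- image$pixel_size
  nr <- nrow(I); nc <- ncol(I)
  bg <- stats::median(I)
  rng <- bg - min(I)
  if (rng < 1e-6 * max(abs(bg), 1) || rng == 0) {
    stop("estimate_walls: no dark line features in image")
  }
  thr <- bg - 0.45 * rng
  sel <- which(I < thr)
  if (length(sel) < 40L) stop("estimate_walls: fewer than two line features found")
  py <- ((sel - 1L) %% nr)        # 0-based pixel coords
  px <- ((sel - 1L) %/% nr)
  wgt <- bg - I[sel]
  diag_len <- ceiling(sqrt(nr^2 + nc^2))
  thetas <- seq(0, 180 - theta_step, by = theta_step) * pi / 180
  rho_off <- diag_len + 1L
  n_rho <- 2L * diag_len + 3L
  acc <- matrix(0, length(thetas), n_rho)
  for (j in seq_along(thetas)) {
    rho <- round(px * cos(thetas[j]) + py * sin(thetas[j])) + rho_off
    s <- rowsum(wgt, rho)
    acc[j, as.integer(rownames(s))] <- s
  }
  pick_peak <- function(a) {
    k <- which.max(a)
    c(row = (k - 1L) %% nrow(a) + 1L, col = (k - 1L) %/% nrow(a) + 1L, val = max(a))
  }
  p1 <- pick_peak(acc)
  # suppress a neighborhood (wrapping in theta) around the first peak
  dtheta_px <- ceiling(6 / theta_step)
  ti <- ((p1["row"] - 1L + seq(-dtheta_px, dtheta_px)) %% nrow(acc)) + 1L
  acc2 <- acc
  acc2[ti, ] <- 0   # suppress near-parallel lines wholesale: the two walls differ in angle
  p2 <- pick_peak(acc2)
  if (p2["val"] < min_rel_peak * p1["val"]) {
    stop("estimate_walls: fewer than two line features found")
  }
  refine <- function(pk) {
    th <- thetas[pk["row"]]
    rho <- pk["col"] - rho_off
    d <- abs(px * cos(th) + py * sin(th) - rho)
    s <- d < 2.5
    if (sum(s) < 10L) s <- d < 4
    wx <- wgt[s]
    cx <- sum(wx * px[s]) / sum(wx)
    cy <- sum(wx * py[s]) / sum(wx)
    X <- cbind(px[s] - cx, py[s] - cy) * sqrt(wx)
    sv <- svd(X, nu = 0)
    dir <- sv$v[, 1]
    list(point = c(cx, cy) * ps, dir = norm_vec(dir))
  }
  l1 <- refine(p1)
  l2 <- refine(p2)
  ang <- function(d) atan2(d[2], d[1])
  # orient both directions into the same half plane before bisecting
  d1 <- l1$dir
  d2 <- if (sum(l1$dir * l2$dir) < 0) -l2$dir else l2$dir
  bis <- norm_vec(d1 + d2)
  half_angle <- acos(pmin(1, abs(sum(d1 * d2)))) / 2 * 180 / pi
  out <- list(l1, l2)
  attr(out, "half_angle_deg") <- half_angle
  attr(out, "axis_angle_deg") <- (ang(bis) * 180 / pi) %% 180
  out
}

bilinear <- function(I, x, y) {
  # x, y in 0-based pixel coordinates; NA outside
  nr <- nrow(I); nc <- ncol(I)
  x0 <- floor(x); y0 <- floor(y)
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 2 & y0 <= nr - 2
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  fx <- x[ok] - x0[ok]; fy <- y[ok] - y0[ok]
  i00 <- (x0[ok]) * nr + y0[ok] + 1
  v <- I[i00] * (1 - fx) * (1 - fy) + I[i00 + nr] * fx * (1 - fy) +
       I[i00 + 1] * (1 - fx) * fy + I[i00 + nr + 1] * fx * fy
  out[ok] <- v
  out
}

#' Detect the membrane profile between the pipette walls
#'
#' For each scan line parallel to the pipette axis (one line per pixel of
#' transverse offset, excluding a margin around each wall), the image is
#' sampled at 1 px spacing, smoothed with a centered rolling mean of
#' `window` samples, and the global intensity minimum is localized; ties
#' break toward the pipette tip.  The minimum is refined to subpixel
#' precision by parabolic interpolation of the three samples around it
#' (disable with `subpixel = FALSE` to reproduce pixel-precision results).
#' Lines whose intensity dip is not prominent enough are skipped.
#'
#' @param image a `patch_image`.
#' @param window rolling-mean window in samples (default 9).
#' @param wall_margin_px exclusion margin around each wall, px.
#' @param min_prominence minimum dip depth as a fraction of the image
#'   intensity range for a line to contribute a point.
#' @param subpixel refine minima by parabolic interpolation.
#' @return data.frame of class `membrane_profile` with columns `x_um`,
#'   `y_um`, `intensity`, `t_um` (transverse offset), `s_um` (axial
#'   position); attributes `walls`, `apex_um`, `axis_dir`.
#' @export
detect_membrane <- function(image, window = 9, wall_margin_px = 5,
                            min_prominence = 0.15, subpixel = TRUE) {
  I <- image$intensities
  ps <- image$pixel_size
  nr <- nrow(I); nc <- ncol(I)
  rng_img <- diff(range(I))
  if (rng_img <= 1e-9) stop("detect_membrane: detection failure (uniform image)")
  walls <- image$wall_lines %||% estimate_walls(image)
  apex <- line_intersection(walls[[1]], walls[[2]])
  d1 <- walls[[1]]$dir
  d2 <- if (sum(walls[[1]]$dir * walls[[2]]$dir) < 0) -walls[[2]]$dir else walls[[2]]$dir
  u <- norm_vec(d1 + d2)
  # orient the axis from the apex toward the image interior
  center <- c((nc - 1) / 2, (nr - 1) / 2) * ps
  if (sum((center - apex) * u) < 0) u <- -u
  v <- c(-u[2], u[1])
  margin <- wall_margin_px * ps
  # scan-line extents in the apex frame
  corner_x <- c(0, (nc - 1) * ps, 0, (nc - 1) * ps)
  corner_y <- c(0, 0, (nr - 1) * ps, (nr - 1) * ps)
  s_corner <- (corner_x - apex[1]) * u[1] + (corner_y - apex[2]) * u[2]
  t_corner <- (corner_x - apex[1]) * v[1] + (corner_y - apex[2]) * v[2]
  s_max <- max(s_corner)
  t_max <- min(max(abs(t_corner)), s_max * tan(pi / 3))
  t_lines <- seq(-t_max, t_max, by = ps)
  s_samp <- seq(0, s_max, by = ps)
  pts <- vector("list", length(t_lines))
  for (j in seq_along(t_lines)) {
    t0 <- t_lines[j]
    gx <- apex[1] + s_samp * u[1] + t0 * v[1]
    gy <- apex[2] + s_samp * u[2] + t0 * v[2]
    vals <- bilinear(I, gx / ps, gy / ps)
    dw <- pmin(line_point_dist(gx, gy, walls[[1]]),
               line_point_dist(gx, gy, walls[[2]]))
    vals[dw < margin] <- NA
    keep <- which(is.finite(vals))
    if (length(keep) < max(window, 5L)) next
    # smooth over the largest contiguous run of valid samples
    runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
    run <- runs[[which.max(lengths(runs))]]
    if (length(run) < max(window, 5L)) next
    sm <- rolling_mean(vals[run], window)
    ref <- stats::quantile(sm, 0.9, names = FALSE)
    k <- which.min(sm)  # first minimum = nearest the tip on ties
    if ((ref - sm[k]) < min_prominence * rng_img) next
    delta <- 0
    if (subpixel && k > 1L && k < length(sm)) {
      den <- sm[k - 1L] - 2 * sm[k] + sm[k + 1L]
      if (den > 1e-12) delta <- 0.5 * (sm[k - 1L] - sm[k + 1L]) / den
      delta <- max(min(delta, 0.5), -0.5)
    }
    s_hat <- s_samp[run[k]] + delta * ps
    pts[[j]] <- c(s = s_hat, t = t0, int = sm[k])
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 3L) {
    stop("detect_membrane: detection failure (fewer than 3 membrane points)")
  }
  out <- data.frame(
    x_um = apex[1] + pts[, "s"] * u[1] + pts[, "t"] * v[1],
    y_um = apex[2] + pts[, "s"] * u[2] + pts[, "t"] * v[2],
    intensity = pts[, "int"],
    t_um = pts[, "t"], s_um = pts[, "s"])
  # enforce the wall-exclusion margin on the detected points themselves:
  # near the attachment the wall and membrane ridges superpose and the
  # localized minimum is pulled toward the wall
  dw_pt <- pmin(line_point_dist(out$x_um, out$y_um, walls[[1]]),
                line_point_dist(out$x_um, out$y_um, walls[[2]]))
  out <- out[dw_pt >= 2 * margin, , drop = FALSE]
  if (nrow(out) < 3L) {
    stop("detect_membrane: detection failure (fewer than 3 membrane points)")
  }
  attr(out, "walls") <- walls
  attr(out, "apex_um") <- apex
  attr(out, "axis_dir") <- u
  class(out) <- c("membrane_profile", "data.frame")
  out
}

#' Least-squares circle fit (algebraic + geometric refinement)
#'
#' Kasa algebraic initialization followed by Levenberg-Marquardt
#' refinement of the orthogonal-distance objective
#' `sum_i (||p_i - center|| - R)^2`.  Near-collinear profiles (fitted
#' curvature below `flat_tol`) are reported as flat: `radius = Inf`,
#' `signed_curvature = 0`.
#'
#' @param points a `membrane_profile`, or a 2-column matrix/data.frame of
#'   (x, y) positions in um.
#' @param orient_point optional reference point (um) on the pipette-tip
#'   side, used to sign the curvature: positive (convex) when the dome
#'   bulges toward it, i.e. the fitted center lies beyond the points.
#' @param flat_tol curvature magnitude (1/um) below which the profile is
#'   reported flat.
#' @return object of class `circle_fit`: `center` (um), `radius` (um),
#'   `rms_um`, `n_points`, `signed_curvature` (1/um), `flat`,
#'   `converged`, `method`.
#' @export
fit_circle <- function(points, orient_point = NULL, flat_tol = FLAT_CURVATURE_TOL) {
  if (inherits(points, "membrane_profile")) {
    if (is.null(orient_point)) orient_point <- attr(points, "apex_um")
    points <- cbind(points$x_um, points$y_um)
  }
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 3L) stop("fit_circle: need at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  scale <- sqrt(mean(xc^2 + yc^2))
  if (scale < 1e-12) stop("fit_circle: degenerate (coincident) points")
  # collinearity via the smallest singular value of the centered cloud
  sv <- svd(cbind(xc, yc), nu = 0)
  flat_now <- function() {
    structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                   rms_um = sqrt(mean((sv$d[2] / sqrt(n))^2)),
                   n_points = n, signed_curvature = 0, flat = TRUE,
                   converged = TRUE, method = "flat"),
              class = "circle_fit")
  }
  if (sv$d[2] < 1e-9 * sv$d[1]) return(flat_now())
  # Kasa: minimize ||x^2 + y^2 - 2ax - 2by - c||
  A <- cbind(2 * xc, 2 * yc, 1)
  b <- xc^2 + yc^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(flat_now())
  a0 <- sol[1]; b0 <- sol[2]
  r0 <- sqrt(max(sol[3] + a0^2 + b0^2, 1e-300))
  # a near-flat profile puts the algebraic center at astronomical distance;
  # skip refinement (the residual ridge has no curvature to follow)
  if (1 / r0 < flat_tol / 2) return(flat_now())
  method <- "algebraic"
  fn <- function(p) sqrt((xc - p[1])^2 + (yc - p[2])^2) - p[3]
  jac <- function(p) {
    d <- sqrt((xc - p[1])^2 + (yc - p[2])^2)
    d <- pmax(d, 1e-12)
    cbind(-(xc - p[1]) / d, -(yc - p[2]) / d, rep(-1, n))
  }
  fit <- lm_fit(function(p) -fn(p), function(p) -jac(p),
                start = c(a0, b0, r0), y = rep(0, n))
  refine_ok <- fit$converged || fit$ss <= sum(fn(c(a0, b0, r0))^2) + 1e-15
  par <- if (refine_ok) fit$par else c(a0, b0, r0)
  method <- if (refine_ok) "geometric" else "algebraic"
  converged <- fit$converged
  center <- c(par[1] + mx, par[2] + my)
  radius <- par[3]
  if (1 / radius < flat_tol) return(flat_now())
  if (!refine_ok) {
    warning("fit_circle: geometric refinement failed; falling back to algebraic fit")
  } else if (!converged) {
    warning("fit_circle: geometric refinement did not converge; using best iterate")
  }
  res <- sqrt((x - center[1])^2 + (y - center[2])^2) - radius
  sgn <- 1
  if (!is.null(orient_point)) {
    dc <- sqrt(sum((center - orient_point)^2))
    dp <- mean(sqrt((x - orient_point[1])^2 + (y - orient_point[2])^2))
    sgn <- if (dc > dp) 1 else -1
  }
  structure(list(center = center, radius = radius,
                 rms_um = sqrt(mean(res^2)), n_points = n,
                 signed_curvature = sgn / radius, flat = FALSE,
                 converged = converged, method = method),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  if (x$flat) {
    cat(sprintf("circle_fit: flat membrane (curvature 0), %d points\n", x$n_points))
  } else {
    cat(sprintf("circle_fit: R = %.4g um, center (%.3g, %.3g) um, rms %.3g um, %d points, curvature %+.4g /um\n",
                x$radius, x$center[1], x$center[2], x$rms_um, x$n_points,
                x$signed_curvature))
  }
  invisible(x)
}

#' Measure the membrane radius of one image end-to-end
#'
#' Convenience wrapper: wall estimation (if needed), membrane detection,
#' and circle fitting with the curvature signed relative to the pipette
#' tip.
#'
#' @inheritParams detect_membrane
#' @param ... passed to [detect_membrane()].
#' @return a `circle_fit`.
#' @export
measure_patch_radius <- function(image, window = 9, ...) {
  prof <- detect_membrane(image, window = window, ...)
  fit_circle(prof)
}
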