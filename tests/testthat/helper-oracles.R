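# Independent oracles and small fixture builders used across tests.

# Exhaustive grid-search circle fit: minimizes the orthogonal-distance
# sum of squares over a (cx, cy, r) grid, coarse pass then 0.01-um
# refinement.  Deliberately independent of fit_circle().
grid_circle_oracle <- function(points, step = 0.01) {
  x <- points[, 1]; y <- points[, 2]
  ss_of <- function(cx, cy, r) sum((sqrt((x - cx)^2 + (y - cy)^2) - r)^2)
  # coarse: around the centroid and mean centroid-distance
  cx0 <- mean(x); cy0 <- mean(y)
  r0 <- mean(sqrt((x - cx0)^2 + (y - cy0)^2))
  span <- max(diff(range(x)), diff(range(y)), r0)
  best <- c(cx0, cy0, r0, ss_of(cx0, cy0, r0))
  search <- function(center, half, st) {
    cxs <- seq(center[1] - half, center[1] + half, by = st)
    cys <- seq(center[2] - half, center[2] + half, by = st)
    rs <- seq(max(center[3] - half, st), center[3] + half, by = st)
    for (cx in cxs) for (cy in cys) {
      d <- sqrt((x - cx)^2 + (y - cy)^2)
      ss <- vapply(rs, function(r) sum((d - r)^2), 0)
      k <- which.min(ss)
      if (ss[k] < best[4]) best <<- c(cx, cy, rs[k], ss[k])
    }
  }
  search(best[1:3], half = span, st = span / 10)
  search(best[1:3], half = span / 8, st = step * 5)
  search(best[1:3], half = step * 6, st = step)
  list(center = best[1:2], radius = best[3], ss = best[4])
}

circle_ss <- function(points, center, radius) {
  sum((sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2) - radius)^2)
}

# points on a circle arc, optionally jittered
arc_points <- function(n, radius, center = c(0, 0), theta = c(0.2, 2.4),
                       jitter_sd = 0, seed = 1) {
  set.seed(seed)
  th <- seq(theta[1], theta[2], length.out = n)
  cbind(center[1] + radius * cos(th) + rnorm(n, 0, jitter_sd),
        center[2] + radius * sin(th) + rnorm(n, 0, jitter_sd))
}

# distance of detected profile points from the true circle, in pixels
profile_circle_err_px <- function(profile, image) {
  ctr <- image$truth$center_um
  r <- image$truth$radius_um
  abs(sqrt((profile$x_um - ctr[1])^2 + (profile$y_um - ctr[2])^2) - r) /
    image$pixel_size
}
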