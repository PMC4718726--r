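# Geometric phantom renderer for patch-pipette images: two dark converging
# wall ridges and a dark membrane arc with Gaussian cross-sections.  This is
# not an optics model (no DIC point-spread simulation); it produces images
# sufficient to exercise the detector with exact ground truth.

# Internal scene layout (pipette frame): s runs along the pipette axis from
# the virtual wall apex into the pipette, t transverse.  Walls are the two
# rays |t| = tip_inner_radius + s*tan(half_angle); the membrane is a circle
# arc of radius |R| attached to the walls at |t| = halfwidth, s = s_m,
# bulging toward the tip for R > 0 (convex) and away for R < 0 (concave).

#' Render a phantom patch image
#'
#' @param geometry a [pipette_geometry()].
#' @param radius signed membrane radius in um: positive = convex dome
#'   (toward tip), negative = concave, `Inf` (or `flat = TRUE`) = flat
#'   chord.  `|radius|` must exceed the tip inner radius.
#' @param image_shape optional `c(rows, cols)` in pixels; computed to fit
#'   the scene when `NULL`.  An explicit shape too small for the arc is an
#'   error.
#' @param noise_sd additive Gaussian intensity noise SD (background is 200,
#'   ridge depth `wall_darkness * 200`).
#' @param seed RNG seed for the noise.
#' @param halfwidth half-width of the membrane attachment chord, um;
#'   default `tip_inner_radius + 0.15 * |radius|`.
#' @param flat render a flat membrane (straight chord).
#' @return object of class `patch_image`: list with `intensities` (matrix,
#'   rows = y), `pixel_size`, `wall_lines`, and `truth` (ground-truth arc
#'   coordinates in um, true radius/center, apex, axis angle).
#' @export
render_patch_image <- function(geometry = pipette_geometry(), radius,
                               image_shape = NULL, noise_sd = 0, seed = 1,
                               halfwidth = NULL, flat = FALSE) {
  stopifnot(inherits(geometry, "pipette_geometry"))
  ps <- geometry$pixel_size
  alpha <- geometry$half_angle * pi / 180
  theta <- geometry$axis_angle * pi / 180
  r_tip <- geometry$tip_inner_radius
  flat <- flat || !is.finite(radius)
  R <- if (flat) Inf else abs(radius)
  convex <- flat || radius > 0
  if (!flat && R < r_tip) {
    stop("render_patch_image: |radius| must be at least the tip inner radius")
  }
  w <- halfwidth %||% if (flat) r_tip + 0.4 else r_tip + 0.15 * R
  if (!flat && w >= 0.97 * R) {
    stop("render_patch_image: arc does not fit the pipette (attachment halfwidth too close to radius); use a larger radius or smaller halfwidth")
  }
  if (w <= r_tip) w <- r_tip + 0.2
  s_m <- (w - r_tip) / tan(alpha)
  if (flat) {
    s_c <- NA_real_
    sag <- 0
  } else {
    h <- sqrt(R^2 - w^2)
    s_c <- if (convex) s_m + h else s_m - h
    sag <- R - h   # dome height above the chord
  }
  s_arc_extreme <- if (flat) s_m else if (convex) s_c - R else s_c + R
  pad <- 0.35
  s_lo <- max(min(s_m, s_arc_extreme) - pad, 0)
  s_hi <- max(s_m, s_arc_extreme) + 1.6
  t_hi <- r_tip + s_hi * tan(alpha) + 0.35
  u <- c(cos(theta), sin(theta))
  v <- c(-sin(theta), cos(theta))
  corners_s <- c(s_lo, s_lo, s_hi, s_hi)
  corners_t <- c(-t_hi, t_hi, -t_hi, t_hi)
  cx <- corners_s * u[1] + corners_t * v[1]
  cy <- corners_s * u[2] + corners_t * v[2]
  apex <- c(pad - min(cx), pad - min(cy))
  need <- c(max(cy) - min(cy), max(cx) - min(cx)) + 2 * pad  # rows, cols in um
  need_px <- ceiling(need / ps)
  if (is.null(image_shape)) {
    image_shape <- need_px
  } else if (any(image_shape < need_px - 1L)) {
    stop(sprintf(
      "render_patch_image: arc does not fit the %dx%d field of view (need %dx%d px)",
      image_shape[1], image_shape[2], need_px[1], need_px[2]))
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  xs <- (seq_len(nc) - 1L) * ps
  ys <- (seq_len(nr) - 1L) * ps
  # pipette-frame coordinates of every pixel (rows = y)
  S <- outer((ys - apex[2]) * u[2], (xs - apex[1]) * u[1], "+")
  Tt <- outer((ys - apex[2]) * v[2], (xs - apex[1]) * v[1], "+")
  bg <- 200
  depth <- geometry$wall_darkness * bg
  sigma_wall <- 1.8 * ps
  sigma_arc <- 1.6 * ps
  d_wall_up <- abs(Tt - (r_tip + S * tan(alpha))) * cos(alpha)
  d_wall_lo <- abs(Tt + (r_tip + S * tan(alpha))) * cos(alpha)
  img <- bg - depth * exp(-d_wall_up^2 / (2 * sigma_wall^2)) -
              depth * exp(-d_wall_lo^2 / (2 * sigma_wall^2))
  # membrane distance field
  if (flat) {
    inside <- abs(Tt) <= w
    d_line <- abs(S - s_m)
    d_end <- sqrt((S - s_m)^2 + (abs(Tt) - w)^2)
    d_arc <- ifelse(inside, d_line, d_end)
  } else {
    dS <- S - s_c
    dc <- sqrt(dS^2 + Tt^2)
    on_sector <- (abs(Tt) / pmax(dc, 1e-12) <= w / R) &
      (if (convex) dS <= 0 else dS >= 0)
    d_circ <- abs(dc - R)
    d_end <- pmin(sqrt((S - s_m)^2 + (Tt - w)^2),
                  sqrt((S - s_m)^2 + (Tt + w)^2))
    d_arc <- ifelse(on_sector, d_circ, d_end)
  }
  img <- img - depth * exp(-d_arc^2 / (2 * sigma_arc^2))
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
  }
  img <- pmin(pmax(img, 0), 255)
  # ground truth in image um coordinates
  tg <- seq(-w * 0.999, w * 0.999, length.out = 201)
  sg <- if (flat) rep(s_m, length(tg)) else {
    if (convex) s_c - sqrt(R^2 - tg^2) else s_c + sqrt(R^2 - tg^2)
  }
  arc_xy <- cbind(x_um = apex[1] + sg * u[1] + tg * v[1],
                  y_um = apex[2] + sg * u[2] + tg * v[2])
  wall_lines <- list(
    list(point = c(apex[1] + r_tip * v[1], apex[2] + r_tip * v[2]),
         dir = norm_vec(u + tan(alpha) * v)),
    list(point = c(apex[1] - r_tip * v[1], apex[2] - r_tip * v[2]),
         dir = norm_vec(u - tan(alpha) * v)))
  center_um <- if (flat) c(NA_real_, NA_real_) else
    c(apex[1] + s_c * u[1], apex[2] + s_c * u[2])
  structure(list(
    intensities = img,
    pixel_size = ps,
    wall_lines = wall_lines,
    truth = list(radius_um = if (flat) Inf else R,
                 signed_radius = radius, convex = convex, flat = flat,
                 center_um = center_um, arc_um = arc_xy,
                 apex_um = apex, axis_angle = geometry$axis_angle,
                 half_angle = geometry$half_angle,
                 halfwidth_um = w, s_membrane_um = s_m)),
    class = "patch_image")
}

norm_vec <- function(x) x / sqrt(sum(x^2))

#' @export
print.patch_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("patch_image: %d x %d px, %.4f um/px (%.1f px/um)\n",
              d[1], d[2], x$pixel_size, 1 / x$pixel_size))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth radius: %s um\n",
                format(x$truth$radius_um, digits = 4)))
  }
  invisible(x)
}
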