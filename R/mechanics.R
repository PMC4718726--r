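# Laplace-law mechanics: geometry + pressure -> lateral membrane tension.

#' Lateral membrane tension from Laplace's law
#'
#' Computes `T = R * dp / 2` with explicit unit handling: radius in um,
#' pressure in mmHg (1 mmHg = 133.322 Pa), tension returned in mN/m.
#' Tension is a symmetric, non-negative quantity: the absolute pressure is
#' used, so equal suction and positive pressure give equal tension.  A flat
#' membrane (infinite radius, `flat = TRUE` or non-finite radius) carries
#' zero Laplace tension by convention.
#'
#' @param radius_um radius of membrane curvature in um (vectorized).
#' @param dp_mmhg applied pressure difference in mmHg (signed).
#' @param flat logical flag (vectorized): membrane is flat; returns 0.
#' @return tension in mN/m.
#' @export
#' @examples
#' laplace_tension(2.87, -20)   # ~3.83 mN/m
#' laplace_tension(1, 15)       # ~1.0 mN/m (unit sanity anchor)
laplace_tension <- function(radius_um, dp_mmhg, flat = FALSE) {
  n <- max(length(radius_um), length(dp_mmhg), length(flat))
  radius_um <- rep_len(radius_um, n)
  dp_mmhg <- rep_len(dp_mmhg, n)
  flat <- rep_len(as.logical(flat), n)
  flat <- flat | !is.finite(radius_um)
  if (any(radius_um[!flat] <= 0)) {
    stop("laplace_tension: radius must be positive (or flagged flat)")
  }
  t <- radius_um * abs(dp_mmhg) * TENSION_COEF
  t[flat] <- 0
  t
}

#' Signed inverse radius (curvature) of a circle fit
#'
#' Returns the signed curvature 1/R in 1/um for a [fit_circle()] result;
#' flat membranes map to exactly 0.  Positive curvature denotes a convex
#' dome (bulging toward the pipette tip, as at rest and under suction),
#' negative denotes concave.
#'
#' @param circle a `circle_fit` object (or a numeric signed radius).
#' @return signed curvature in 1/um.
#' @export
inverse_radius <- function(circle) {
  if (inherits(circle, "circle_fit")) {
    if (isTRUE(circle$flat)) return(0)
    return(circle$signed_curvature)
  }
  r <- as.numeric(circle)
  ifelse(is.finite(r) & r != 0, 1 / r, 0)
}

#' Join circle fits with pressures into a tension table
#'
#' @param circles data.frame with `cell_id`, `sweep_id`, `radius_um` and
#'   optional logical `flat` columns.
#' @param pressures data.frame with `cell_id`, `sweep_id`, `dp_mmhg`.
#' @param drop_flat drop flat-membrane rows instead of assigning tension 0.
#' @return merged data.frame with a `tension_mN_per_m` column.
#' @export
tension_table <- function(circles, pressures, drop_flat = FALSE) {
  d <- merge(circles, pressures, by = c("cell_id", "sweep_id"))
  flat <- if ("flat" %in% names(d)) d$flat else !is.finite(d$radius_um)
  d$tension_mN_per_m <- laplace_tension(d$radius_um, d$dp_mmhg, flat = flat)
  if (drop_flat) d <- d[!flat, , drop = FALSE]
  d
}
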