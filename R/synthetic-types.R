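# Parameter containers for the synthetic-data generator.  Defaults encode
# the experimental regime the analysis assumes: HEK293T-style cell-attached
# patches imaged at 61.5 px/um in pipettes angled ~15 deg, channels with
# half-activation tension of a few mN/m, inactivation over tens of ms and
# recovery over seconds, resting tension 0.5-4 mN/m, and membrane flattening
# near +5 to +6 mmHg.

#' Pipette geometry for the image phantom
#'
#' @param half_angle taper half-angle of the pipette walls, degrees.
#' @param tip_inner_radius inner radius at the tip region, um.  Also the
#'   lower bound on dome radius (a dome cannot be smaller than the
#'   hemisphere spanning the tip).
#' @param axis_angle pipette axis angle relative to image rows, degrees.
#' @param wall_darkness wall/membrane contrast as a fraction of background.
#' @param pixel_size um per pixel (default 1/61.5).
#' @return object of class `pipette_geometry`.
#' @export
pipette_geometry <- function(half_angle = 10, tip_inner_radius = 2.2,
                             axis_angle = 15, wall_darkness = 0.6,
                             pixel_size = 1 / 61.5) {
  stopifnot_scalar_pos(half_angle, "half_angle")
  stopifnot_scalar_pos(tip_inner_radius, "tip_inner_radius")
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot(half_angle < 45, wall_darkness > 0, wall_darkness <= 1)
  structure(list(half_angle = half_angle, tip_inner_radius = tip_inner_radius,
                 axis_angle = axis_angle, wall_darkness = wall_darkness,
                 pixel_size = pixel_size),
            class = "pipette_geometry")
}

#' Membrane dome model: curvature as a function of pressure
#'
#' Signed curvature follows a strictly monotone decreasing map that equals
#' `1/r_rest` at dp = 0, crosses zero at `dp_flat` (the pressure that
#' flattens the dome), and saturates smoothly at magnitude `1/min_radius`
#' (the dome cannot curve tighter than the hemisphere spanning the pipette
#' opening):
#'   c(dp) = c_max * tanh( (1 - dp/dp_flat) * atanh(c_rest/c_max) )
#' Positive curvature = convex (dome bulging toward the tip).
#'
#' @param r_rest resting dome radius at dp = 0, um.
#' @param dp_flat pressure (mmHg) at which the membrane is flat; +5.5 by
#'   default (between the +5 and +6 mmHg at which release currents peak).
#' @param min_radius smallest attainable dome radius, um (pipette opening).
#' @return object of class `membrane_model`.
#' @export
membrane_model <- function(r_rest = 3.5, dp_flat = 5.5, min_radius = 2.2) {
  stopifnot_scalar_pos(r_rest, "r_rest")
  stopifnot_scalar_pos(dp_flat, "dp_flat")
  stopifnot_scalar_pos(min_radius, "min_radius")
  if (min_radius >= r_rest) stop("membrane_model: min_radius must be < r_rest")
  structure(list(r_rest = r_rest, dp_flat = dp_flat, min_radius = min_radius),
            class = "membrane_model")
}

#' Signed membrane curvature at a given pressure
#'
#' @param membrane a [membrane_model()].
#' @param dp_mmhg applied pressure (mmHg), vectorized.
#' @return signed curvature in 1/um (positive = convex toward tip).
#' @export
membrane_curvature <- function(membrane, dp_mmhg) {
  c_rest <- 1 / membrane$r_rest
  c_max <- 1 / membrane$min_radius
  u <- (1 - dp_mmhg / membrane$dp_flat) * atanh(c_rest / c_max)
  c_max * tanh(u)
}

#' Dome radius at a given pressure
#'
#' @inheritParams membrane_curvature
#' @return radius in um; `Inf` where the membrane is flat (|curvature|
#'   below the flat threshold).
#' @export
membrane_radius <- function(membrane, dp_mmhg) {
  cc <- abs(membrane_curvature(membrane, dp_mmhg))
  ifelse(cc < FLAT_CURVATURE_TOL, Inf, 1 / cc)
}

#' Channel gating parameters
#'
#' Two-variable gating: instantaneous open probability follows a Boltzmann
#' in tension; a slow availability variable captures inactivation (time
#' constant `tau_inact`, tens of ms) and recovery at low tension
#' (`tau_rec`, seconds).  Steady-state availability decreases with tension
#' as a falling sigmoid centered at `inact_t50`.
#'
#' @param t50 half-activation tension, mN/m.
#' @param k activation slope factor, mN/m.
#' @param i_max saturating peak current scale, pA.
#' @param tau_inact inactivation time constant, s.
#' @param tau_rec recovery time constant at near-zero tension, s.
#' @param t_rest resting tension of the patch, mN/m (the 0.5-4 mN/m range
#'   typical of gigaseal patches).
#' @param t_rest_range range from which per-cell resting tensions are drawn.
#' @param inact_t50 tension of half-maximal steady-state inactivation, mN/m.
#' @param inact_k slope of the steady-state availability curve, mN/m.
#' @return object of class `channel_params`.
#' @export
channel_params <- function(t50 = 2.7, k = 0.8, i_max = 300,
                           tau_inact = 0.025, tau_rec = 2.4,
                           t_rest = 2.0, t_rest_range = c(0.5, 4.0),
                           inact_t50 = 1.5, inact_k = 0.25) {
  for (nm in c("t50", "k", "i_max", "tau_inact", "tau_rec", "inact_t50", "inact_k")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (tau_rec <= tau_inact) {
    stop("channel_params: tau_rec must greatly exceed tau_inact")
  }
  stopifnot(t_rest >= 0, length(t_rest_range) == 2L, t_rest_range[1] >= 0,
            diff(t_rest_range) >= 0)
  structure(list(t50 = t50, k = k, i_max = i_max, tau_inact = tau_inact,
                 tau_rec = tau_rec, t_rest = t_rest,
                 t_rest_range = t_rest_range,
                 inact_t50 = inact_t50, inact_k = inact_k),
            class = "channel_params")
}

#' Pressure-step protocol
#'
#' A protocol is an ordered sequence of constant-pressure segments.
#'
#' @param amplitude segment pressures, mmHg.
#' @param duration_s segment durations, s (recycled).
#' @param inter_sweep_s interval between sweeps, s (10 s allows recovery
#'   from inactivation between stimuli).
#' @param sample_rate sampling rate, Hz.
#' @return object of class `pressure_protocol` (data.frame of segments with
#'   attributes).
#' @export
pressure_protocol <- function(amplitude, duration_s, inter_sweep_s = 10,
                              sample_rate = 5000) {
  stopifnot(length(amplitude) >= 1L, all(duration_s > 0))
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  seg <- data.frame(amplitude = amplitude,
                    duration_s = rep_len(duration_s, length(amplitude)))
  structure(seg, inter_sweep_s = inter_sweep_s, sample_rate = sample_rate,
            class = c("pressure_protocol", "data.frame"))
}

#' Standard test-step protocol: hold, step, hold
#'
#' @param step_mmhg test-step amplitude, mmHg.
#' @param step_s step duration, s (300 ms default).
#' @param pre_s,post_s zero-pressure holds before/after the step, s.
#' @param sample_rate sampling rate, Hz.
#' @return a [pressure_protocol()].
#' @export
step_protocol <- function(step_mmhg, step_s = 0.3, pre_s = 0.1, post_s = 0.5,
                          sample_rate = 5000) {
  pressure_protocol(c(0, step_mmhg, 0), c(pre_s, step_s, post_s),
                    sample_rate = sample_rate)
}

#' Conditioning-prepulse protocol: hold, prepulse, release (optional test step)
#'
#' @param prepulse_mmhg prepulse amplitude, mmHg.
#' @param prepulse_s prepulse duration, s (5 s default).
#' @param test_mmhg optional test-step amplitude after release, mmHg.
#' @param test_s test-step duration, s.
#' @param pre_s,post_s zero-pressure holds, s.
#' @param sample_rate sampling rate, Hz.
#' @return a [pressure_protocol()].
#' @export
prepulse_protocol <- function(prepulse_mmhg, prepulse_s = 5, test_mmhg = NULL,
                              test_s = 0.3, pre_s = 0.1, post_s = 0.5,
                              sample_rate = 5000) {
  amp <- c(0, prepulse_mmhg)
  dur <- c(pre_s, prepulse_s)
  if (!is.null(test_mmhg)) {
    amp <- c(amp, test_mmhg)
    dur <- c(dur, test_s)
  }
  pressure_protocol(c(amp, 0), c(dur, post_s), sample_rate = sample_rate)
}

#' Full simulation configuration
#'
#' @param seed integer master seed; per-cell and per-sweep streams are
#'   derived deterministically from it so subsets are reproducible.
#' @param n_cells number of cells/patches.
#' @param responses_total total responses across cells (pressure series are
#'   subsampled per cell to hit this count); `NULL` uses every pressure for
#'   every cell.
#' @param geometry a [pipette_geometry()].
#' @param membrane a [membrane_model()].
#' @param channel a [channel_params()].
#' @param noise_current additive Gaussian SD on peak currents and trace
#'   samples, pA.
#' @param noise_radius additive Gaussian SD on measured radii, um.
#' @param cell_heterogeneity fractional between-cell SD applied to the
#'   channel `t50` (additive normal, SD = fraction * t50) and `i_max`
#'   (multiplicative lognormal, sdlog = fraction).
#' @param radius_spread fractional lognormal between-cell spread of the
#'   membrane geometry (resting and minimal radii), reflecting pipette-to-
#'   pipette variation.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_cells = 15, responses_total = NULL,
                              geometry = pipette_geometry(),
                              membrane = membrane_model(),
                              channel = channel_params(),
                              noise_current = 10, noise_radius = 0.05,
                              cell_heterogeneity = 0.08,
                              radius_spread = 0.12) {
  stopifnot(inherits(geometry, "pipette_geometry"),
            inherits(membrane, "membrane_model"),
            inherits(channel, "channel_params"),
            noise_current >= 0, noise_radius >= 0,
            cell_heterogeneity >= 0, radius_spread >= 0,
            n_cells >= 1)
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 responses_total = responses_total,
                 geometry = geometry, membrane = membrane, channel = channel,
                 noise_current = noise_current, noise_radius = noise_radius,
                 cell_heterogeneity = cell_heterogeneity,
                 radius_spread = radius_spread),
            class = "simulation_config")
}

#' Generative cohort settings per recording condition
#'
#' Canned generative (ground-truth) parameter sets for the five cohort
#' conditions the pipeline reproduces: cell-attached and inside-out
#' negative-pressure tension series, and the three conditioning-prepulse
#' series (0, +5, +10 mmHg prepulse).  Midpoints, slopes, cohort sizes and
#' normalization mode are the package defaults for each condition.
#'
#' @param condition one of `"cell_attached"`, `"inside_out"`,
#'   `"prepulse_0"`, `"prepulse_5"`, `"prepulse_10"`.
#' @return list with `t50`, `k`, `n_cells`, `n_responses`, `pressures`
#'   (mmHg test steps), and `normalize` mode.
#' @export
condition_params <- function(condition = c("cell_attached", "inside_out",
                                           "prepulse_0", "prepulse_5",
                                           "prepulse_10")) {
  condition <- match.arg(condition)
  switch(condition,
    cell_attached = list(t50 = 2.7, k = 0.8, n_cells = 15L, n_responses = 218L,
                         pressures = seq(-4, -60, by = -4),
                         normalize = "plateau_of_fit"),
    inside_out = list(t50 = 4.7, k = 1.2, n_cells = 10L, n_responses = 123L,
                      pressures = seq(-5, -65, by = -5),
                      normalize = "plateau_of_fit"),
    prepulse_0 = list(t50 = 2.2, k = 0.8, n_cells = 11L, n_responses = 121L,
                      pressures = seq(0, -50, by = -5),
                      normalize = "max_response"),
    prepulse_5 = list(t50 = 1.4, k = 0.7, n_cells = 11L, n_responses = 121L,
                      pressures = seq(0, -50, by = -5),
                      normalize = "max_response"),
    prepulse_10 = list(t50 = 1.8, k = 1.1, n_cells = 11L, n_responses = 121L,
                       pressures = seq(0, -50, by = -5),
                       normalize = "max_response"))
}
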