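# Simulators: per-response cohorts, full current traces, recovery-duration
# series, and pressure-domain cohorts.  All are deterministic given their
# seed; per-cell streams are derived with derive_seed() so any subset of
# cells reproduces independently of the others.

# Steady-state availability: falling sigmoid in tension.
avail_inf <- function(channel, tension) {
  1 / (1 + exp((tension - channel$inact_t50) / channel$inact_k))
}

# Tension seen by the gating model.  Two additive components:
#   * a resting component t_rest * |dp - dp_flat| / dp_flat that equals the
#     patch resting tension at dp = 0, falls linearly to exactly 0 at the
#     flattening pressure (which is what lets channels recover during a
#     flattening prepulse), and rises again on the concave side;
#   * for suction (dp < 0), the Laplace tension of the dome at its
#     pressure-dependent radius (well behaved: under suction the radius
#     saturates toward the pipette opening).
# Laplace tension with the raw applied pressure cannot be used near
# dp_flat -- the radius diverges there while dp stays finite -- so this
# decomposition is a documented model choice, not a measured relation.
gating_tension <- function(membrane, channel, dp_mmhg) {
  base <- channel$t_rest * abs(dp_mmhg - membrane$dp_flat) / membrane$dp_flat
  suction <- ifelse(dp_mmhg < 0,
                    laplace_tension(membrane_radius(membrane, pmin(dp_mmhg, 0)),
                                    dp_mmhg),
                    0)
  base + suction
}

#' Simulate a cohort of per-response peak-current records
#'
#' For each cell, a pressure series is assigned (an evenly spaced
#' subsample of the condition's step series, so every cell spans
#' sub-threshold to saturating tension), the dome radius follows the
#' membrane curvature map with per-cell geometric spread, the true tension
#' is computed through Laplace's law from the true radius and pressure, and
#' the mean peak current is `i_max_cell * Boltzmann(T; t50_cell, k)`.
#' Gaussian noise is then added to the peak (pA) and to the measured
#' radius (um).
#'
#' @param config a [simulation_config()].
#' @param condition recording condition; selects the generative (t50, k)
#'   pair and cohort size via [condition_params()].  Fields already set in
#'   `config` (n_cells, responses_total, channel t50/k) win when
#'   `override = FALSE`.
#' @param override replace config cohort/channel settings with the
#'   condition defaults (default TRUE).
#' @return data.frame with columns `cell_id`, `sweep_id`, `dp_mmhg`,
#'   `radius_true_um`, `radius_um` (measured), `tension_true`, `peak_pa`,
#'   plus attributes `generative` (true parameters) and `condition`.
#' @export
simulate_response_set <- function(config = simulation_config(),
                                  condition = "cell_attached",
                                  override = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  cp <- condition_params(condition)
  n_cells <- if (override) cp$n_cells else config$n_cells
  n_total <- if (override) cp$n_responses else
    (config$responses_total %||% (n_cells * length(cp$pressures)))
  ch <- config$channel
  if (override) { ch$t50 <- cp$t50; ch$k <- cp$k }
  grid <- cp$pressures
  # distribute the response budget across cells, remainder to leading cells
  base <- n_total %/% n_cells
  n_per <- rep(base, n_cells) + c(rep(1L, n_total %% n_cells),
                                  rep(0L, n_cells - n_total %% n_cells))
  if (any(n_per > length(grid))) {
    grid <- grid # cells may repeat pressures if budget exceeds the series
  }
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell_seed <- derive_seed(config$seed, 1000L, i)
    rows[[i]] <- with_seed(cell_seed, {
      t50_cell <- ch$t50 + stats::rnorm(1, 0, config$cell_heterogeneity * ch$t50)
      t50_cell <- max(t50_cell, 0.1 * ch$t50)
      imax_cell <- ch$i_max * exp(stats::rnorm(1, 0, config$cell_heterogeneity))
      geom_fac <- exp(stats::rnorm(1, 0, config$radius_spread))
      memb_cell <- membrane_model(r_rest = config$membrane$r_rest * geom_fac,
                                  dp_flat = config$membrane$dp_flat,
                                  min_radius = config$membrane$min_radius * geom_fac)
      if (n_per[i] <= length(grid)) {
        idx <- unique(round(seq(1, length(grid), length.out = n_per[i])))
        # evenly spaced subsample keeps the endpoints (threshold + saturation)
        while (length(idx) < n_per[i]) idx <- sort(c(idx, setdiff(seq_along(grid), idx)[1]))
        dps <- grid[idx]
      } else {
        dps <- grid[((seq_len(n_per[i]) - 1L) %% length(grid)) + 1L]
      }
      r_true <- membrane_radius(memb_cell, dps)
      flat <- !is.finite(r_true)
      t_true <- laplace_tension(r_true, dps, flat = flat)
      mean_peak <- boltzmann(t_true, imax_cell, t50_cell, ch$k)
      peak <- mean_peak + stats::rnorm(length(dps), 0, config$noise_current)
      r_meas <- ifelse(flat, Inf, r_true + stats::rnorm(length(dps), 0, config$noise_radius))
      data.frame(cell_id = sprintf("cell%02d", i),
                 sweep_id = seq_along(dps),
                 dp_mmhg = dps,
                 radius_true_um = r_true,
                 radius_um = r_meas,
                 tension_true = t_true,
                 peak_pa = peak,
                 t50_cell = t50_cell,
                 i_max_cell = imax_cell)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generative") <- list(t50 = ch$t50, k = ch$k, i_max = ch$i_max,
                                  n_cells = n_cells, n_responses = nrow(out))
  attr(out, "condition") <- condition
  out
}

#' Simulate one pressure-clamp current sweep
#'
#' Integrates the two-variable gating model over the protocol's constant-
#' pressure segments.  Open probability responds instantaneously to
#' tension, `p_o = 1/(1 + exp(-(T - t50)/k))`; availability relaxes toward
#' its tension-dependent steady state with time constant `tau_inact` when
#' inactivating (availability falling, high tension) and `tau_rec` when
#' recovering (availability rising, low tension).  Within each segment the
#' tension is constant so the relaxation is integrated exactly (no solver
#' instability is possible); current is `-i_max * p_o * a` (negative =
#' inward at -80 mV) plus optional sample noise.
#'
#' @param protocol a [pressure_protocol()].
#' @param channel a [channel_params()].
#' @param membrane a [membrane_model()].
#' @param seed RNG seed for sample noise.
#' @param noise_current per-sample Gaussian noise SD, pA.
#' @param a0 initial availability; default steady state at the resting
#'   tension (the patch has equilibrated during the inter-sweep interval).
#' @return a `sweep_record` data.frame with columns `time_s`,
#'   `current_pa`, `pressure_mmhg` and attributes `sample_rate`,
#'   `availability`, `segments`.
#' @export
simulate_trace <- function(protocol, channel = channel_params(),
                           membrane = membrane_model(), seed = 1,
                           noise_current = 0, a0 = NULL) {
  stopifnot(inherits(protocol, "pressure_protocol"))
  fs <- attr(protocol, "sample_rate")
  dt <- 1 / fs
  if (!is.finite(dt) || dt <= 0) stop("simulate_trace: invalid sample rate")
  seg_n <- pmax(1L, as.integer(round(protocol$duration_s * fs)))
  dp <- rep(protocol$amplitude, seg_n)
  n <- length(dp)
  tension_seg <- gating_tension(membrane, channel, protocol$amplitude)
  p_o_seg <- 1 / (1 + exp(-(tension_seg - channel$t50) / channel$k))
  a_inf_seg <- avail_inf(channel, tension_seg)
  a <- numeric(n)
  a_cur <- a0 %||% avail_inf(channel, gating_tension(membrane, channel, 0))
  pos <- 0L
  for (s in seq_len(nrow(protocol))) {
    ai <- a_inf_seg[s]
    tau <- if (ai < a_cur) channel$tau_inact else channel$tau_rec
    tt <- seq_len(seg_n[s]) * dt
    seg_a <- ai + (a_cur - ai) * exp(-tt / tau)
    a[pos + seq_len(seg_n[s])] <- seg_a
    a_cur <- seg_a[seg_n[s]]
    pos <- pos + seg_n[s]
  }
  p_o <- rep(p_o_seg, seg_n)
  current <- -channel$i_max * p_o * a
  if (noise_current > 0) {
    current <- current + with_seed(seed, stats::rnorm(n, 0, noise_current))
  }
  rec <- data.frame(time_s = (seq_len(n) - 1L) * dt,
                    current_pa = current,
                    pressure_mmhg = dp)
  seg_end <- cumsum(seg_n) * dt
  seg_start <- c(0, seg_end[-length(seg_end)])
  attr(rec, "sample_rate") <- fs
  attr(rec, "availability") <- a
  attr(rec, "segments") <- data.frame(amplitude = protocol$amplitude,
                                      start_s = seg_start, end_s = seg_end)
  class(rec) <- c("sweep_record", "data.frame")
  rec
}

#' Simulate normalized off-response peaks versus prepulse duration
#'
#' Draws per-patch peak series from the saturating-exponential recovery
#' model `I(t) = i_max - A * exp(-(t - t0)/tau)` with additive Gaussian
#' noise, then normalizes each patch to its own maximal response.
#'
#' @param durations prepulse durations, s.
#' @param n_patches number of patches.
#' @param i_max,A,tau recovery-model parameters (normalized units, s).
#' @param t0 reference duration, s; default the shortest duration.
#' @param noise_sd Gaussian noise SD (normalized units).
#' @param seed RNG seed.
#' @return data.frame `patch_id`, `duration_s`, `peak_norm` with attribute
#'   `generative`.
#' @export
simulate_recovery_peaks <- function(durations = c(0.3, 0.5, 1, 1.5, 2, 3, 4, 5, 7, 10),
                                    n_patches = 11, i_max = 0.82, A = 0.49,
                                    tau = 2.4, t0 = NULL, noise_sd = 0.05,
                                    seed = 1) {
  t0 <- t0 %||% min(durations)
  rows <- lapply(seq_len(n_patches), function(i) {
    with_seed(derive_seed(seed, 2000L, i), {
      mu <- i_max - A * exp(-(durations - t0) / tau)
      y <- mu + stats::rnorm(length(durations), 0, noise_sd)
      data.frame(patch_id = sprintf("patch%02d", i),
                 duration_s = durations,
                 peak_norm = y / max(y))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generative") <- list(i_max = i_max, A = A, tau = tau, t0 = t0,
                                  noise_sd = noise_sd)
  out
}

#' Simulate a negative-pressure cohort in the pressure domain
#'
#' Per-cell half-activation pressures are drawn from a normal distribution
#' centered on `p50_mean` with between-cell SD `p50_se * sqrt(n_cells)`
#' (the spread implied by a reported standard error of the mean),
#' truncated to physical (negative-going) values by rejection.  Each
#' cell's peak-current series over the step protocol follows a Boltzmann
#' in pressure magnitude plus peak noise.
#'
#' @param n_cells number of cells.
#' @param p50_mean cohort mean half-activation pressure, mmHg (signed).
#' @param p50_se reported standard error of the cohort mean, mmHg.
#' @param k_p pressure-domain slope factor, mmHg.
#' @param pressures test pressures, mmHg.
#' @param i_max saturating current, pA.
#' @param noise_current peak noise SD, pA.
#' @param seed RNG seed.
#' @return data.frame `cell_id`, `dp_mmhg`, `peak_pa` with attribute
#'   `generative` including the per-cell true P50s.
#' @export
simulate_pressure_cohort <- function(n_cells = 15, p50_mean = -16.7,
                                     p50_se = 2.8, k_p = 3,
                                     pressures = seq(0, -50, by = -5),
                                     i_max = 300, noise_current = 10,
                                     seed = 1) {
  sd_cell <- p50_se * sqrt(n_cells)
  sgn <- sign(p50_mean)
  rows <- vector("list", n_cells)
  p50_true <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    sim <- with_seed(derive_seed(seed, 3000L, i), {
      m <- -1
      while (m <= 0.5) m <- stats::rnorm(1, abs(p50_mean), sd_cell)
      mean_peak <- boltzmann(abs(pressures), i_max, m, k_p)
      list(m = m,
           df = data.frame(cell_id = sprintf("cell%02d", i),
                           dp_mmhg = pressures,
                           peak_pa = mean_peak +
                             stats::rnorm(length(pressures), 0, noise_current)))
    })
    p50_true[i] <- sgn * sim$m
    rows[[i]] <- sim$df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generative") <- list(p50_mean = p50_mean, p50_se = p50_se,
                                  k_p = k_p, i_max = i_max,
                                  p50_true = p50_true)
  out
}
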