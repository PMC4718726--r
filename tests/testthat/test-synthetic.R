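test_that("parameter containers validate their invariants", {
  expect_error(pipette_geometry(half_angle = -1), "half_angle")
  expect_error(membrane_model(r_rest = 2, min_radius = 3), "min_radius")
  expect_error(channel_params(tau_rec = 0.01, tau_inact = 0.025), "tau_rec")
  expect_error(pressure_protocol(-20, duration_s = 0), "duration")
  expect_error(simulation_config(noise_current = -1))
})

test_that("membrane curvature map is monotone, crosses zero at dp_flat, and is bounded", {
  mb <- membrane_model(r_rest = 3.5, dp_flat = 5.5, min_radius = 2.2)
  dp <- seq(-60, 20, by = 0.25)
  cc <- membrane_curvature(mb, dp)
  expect_true(all(diff(cc) < 0))                      # strictly decreasing in dp
  expect_equal(membrane_curvature(mb, 0), 1 / 3.5)    # resting radius
  expect_equal(membrane_curvature(mb, 5.5), 0)        # flat at dp_flat
  expect_true(all(abs(cc) < 1 / 2.2))                 # bounded by the tip radius
  expect_identical(membrane_radius(mb, 5.5), Inf)
})

test_that("simulate_response_set is deterministic and honors the noise-free limit", {
  cfg <- simulation_config(seed = 4)
  r1 <- simulate_response_set(cfg, "cell_attached")
  r2 <- simulate_response_set(cfg, "cell_attached")
  expect_identical(r1, r2)
  expect_false(identical(
    r1$peak_pa,
    simulate_response_set(simulation_config(seed = 5), "cell_attached")$peak_pa))
  # zero noise, zero heterogeneity: peaks sit exactly on the Boltzmann curve
  cfg0 <- simulation_config(seed = 4, noise_current = 0, noise_radius = 0,
                            cell_heterogeneity = 0, radius_spread = 0)
  r0 <- simulate_response_set(cfg0, "cell_attached")
  gen <- attr(r0, "generative")
  expect_equal(r0$peak_pa,
               boltzmann(r0$tension_true, gen$i_max, gen$t50, gen$k),
               tolerance = 1e-12)
  expect_identical(r0$radius_um, r0$radius_true_um)
})

test_that("cohort sizes and spans match the condition definitions", {
  for (cnd in c("cell_attached", "inside_out", "prepulse_5")) {
    cp <- condition_params(cnd)
    resp <- simulate_response_set(simulation_config(seed = 2), cnd)
    expect_equal(nrow(resp), cp$n_responses)
    expect_equal(length(unique(resp$cell_id)), cp$n_cells)
    # every cell spans sub-threshold to saturating tension
    rng <- do.call(rbind, lapply(split(resp, resp$cell_id), function(d)
      range(d$tension_true)))
    expect_true(all(rng[, 1] < cp$t50 - 1))
    expect_true(all(rng[, 2] > cp$t50 + 1))
  }
})

test_that("zero tension responses equal the Boltzmann intercept", {
  cfg0 <- simulation_config(seed = 1, noise_current = 0, noise_radius = 0,
                            cell_heterogeneity = 0, radius_spread = 0)
  r0 <- simulate_response_set(cfg0, "prepulse_0")
  gen <- attr(r0, "generative")
  at0 <- r0$peak_pa[r0$tension_true == 0]
  expect_gt(length(at0), 0)
  expect_equal(at0, rep(gen$i_max / (1 + exp(gen$t50 / gen$k)), length(at0)),
               tolerance = 1e-12)
})

test_that("simulate_trace is deterministic and sign-correct", {
  pr <- step_protocol(-40)
  t1 <- simulate_trace(pr, seed = 3, noise_current = 1)
  t2 <- simulate_trace(pr, seed = 3, noise_current = 1)
  expect_identical(t1$current_pa, t2$current_pa)
  # inward currents are negative at -80 mV
  expect_lt(min(t1$current_pa), 0)
  expect_equal(nrow(t1), 0.9 * 5000)
})

test_that("saturating steps peak then decay with tau_inact", {
  ch <- channel_params()
  tr <- simulate_trace(step_protocol(-50, step_s = 0.2), ch, membrane_model())
  pk <- measure_peaks(tr, fit_decay = TRUE)
  expect_gt(pk$peak_on_pa, 10)
  expect_equal(pk$decay_tau_s, ch$tau_inact, tolerance = 0.1 * ch$tau_inact)
})

test_that("trace peaks agree with the closed-form response model", {
  # low resting tension so the resting open probability is negligible,
  # which is the regime where peak ~ i_max * Boltzmann(T) * a_rest holds
  ch <- channel_params(t_rest = 0.1)
  mb <- membrane_model()
  tr <- simulate_trace(step_protocol(-50, step_s = 0.3), ch, mb)
  a_rest <- 1 / (1 + exp((patchtension:::gating_tension(mb, ch, 0) - ch$inact_t50) / ch$inact_k))
  T_step <- patchtension:::gating_tension(mb, ch, -50)
  expected <- ch$i_max * boltzmann(T_step, 1, ch$t50, ch$k) * a_rest
  pk <- measure_peaks(tr)
  expect_equal(pk$peak_on_pa, expected, tolerance = 0.05 * expected)
})

test_that("release currents are largest for prepulses at the flattening pressure", {
  ch <- channel_params()
  mb <- membrane_model()
  amps <- 0:10
  offs <- vapply(amps, function(a) {
    tr <- simulate_trace(prepulse_protocol(a, 5), ch, mb)
    measure_peaks(tr, baseline_window = c(0, 0.1), step_window = c(0.1, 5.1),
                  off_window = c(5.1, 5.6))$peak_off_pa
  }, 0)
  best <- amps[which.max(offs)]
  expect_lte(abs(best - mb$dp_flat), 1)        # 5 or 6 for dp_flat = 5.5
  # U shape: both extremes below the maximum
  expect_lt(offs[1], max(offs))
  expect_lt(offs[11], max(offs))
  # off-response after a flattening prepulse exceeds the on-response
  tr5 <- simulate_trace(prepulse_protocol(5, 5), ch, mb)
  pk5 <- measure_peaks(tr5, baseline_window = c(0, 0.1),
                       step_window = c(0.1, 5.1), off_window = c(5.1, 5.6))
  expect_gt(pk5$peak_off_pa, pk5$peak_on_pa)
})

test_that("off-response growth with prepulse duration follows tau_rec", {
  ch <- channel_params()
  mb <- membrane_model()
  durs <- c(0.3, 0.5, 1, 2, 3, 5, 7, 10)
  offs <- vapply(durs, function(d) {
    tr <- simulate_trace(prepulse_protocol(mb$dp_flat, d), ch, mb)
    measure_peaks(tr, baseline_window = c(0, 0.1),
                  step_window = c(0.1, 0.1 + d),
                  off_window = c(0.1 + d, 0.6 + d))$peak_off_pa
  }, 0)
  f <- fit_recovery(durs, offs / max(offs))
  expect_equal(f$tau, ch$tau_rec, tolerance = 0.05 * ch$tau_rec)
})

test_that("availability recovers toward 1 at zero tension", {
  ch <- channel_params()
  tr <- simulate_trace(pressure_protocol(5.5, 30), ch, membrane_model())
  expect_gt(utils::tail(attr(tr, "availability"), 1), 0.99)
})

test_that("recovery-peak generator matches its exponential model", {
  rec <- simulate_recovery_peaks(noise_sd = 0, n_patches = 2, seed = 1)
  gen <- attr(rec, "generative")
  one <- rec[rec$patch_id == "patch01", ]
  mu <- gen$i_max - gen$A * exp(-(one$duration_s - gen$t0) / gen$tau)
  expect_equal(one$peak_norm, mu / max(mu), tolerance = 1e-12)
  # determinism
  expect_identical(simulate_recovery_peaks(seed = 6), simulate_recovery_peaks(seed = 6))
})

test_that("pressure cohorts center on the requested P50", {
  pc <- simulate_pressure_cohort(n_cells = 40, seed = 2)
  gen <- attr(pc, "generative")
  expect_equal(length(gen$p50_true), 40)
  expect_true(all(gen$p50_true < 0))
  expect_equal(mean(gen$p50_true), -16.7, tolerance = 6)
  expect_identical(simulate_pressure_cohort(seed = 3), simulate_pressure_cohort(seed = 3))
})
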