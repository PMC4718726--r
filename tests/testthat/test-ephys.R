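test_that("saturating sweeps with full availability report the full current", {
  # near-ideal channel: no resting tension/current, no steady-state
  # inactivation, steep activation
  ch <- channel_params(i_max = 100, t_rest = 0, inact_t50 = 50, k = 0.4)
  tr <- simulate_trace(step_protocol(-60, step_s = 0.2), ch, membrane_model())
  pk <- measure_peaks(tr)
  expect_equal(pk$peak_on_pa, 100, tolerance = 0.5)
})

test_that("zero-pressure sweeps yield zero peaks", {
  tr <- simulate_trace(step_protocol(0), channel_params(), membrane_model())
  pk <- measure_peaks(tr)
  expect_identical(pk$peak_on_pa, 0)
  expect_identical(pk$peak_off_pa, 0)
})

test_that("peaks are invariant to a constant baseline offset", {
  tr <- simulate_trace(step_protocol(-30), channel_params(), membrane_model(),
                       noise_current = 0.5, seed = 2)
  pk0 <- measure_peaks(tr)
  for (off in c(-50, 13.7)) {
    tr2 <- tr
    tr2$current_pa <- tr2$current_pa + off
    pk <- measure_peaks(tr2)
    expect_equal(pk$peak_on_pa, pk0$peak_on_pa, tolerance = 1e-9)
    expect_equal(pk$peak_off_pa, pk0$peak_off_pa, tolerance = 1e-9)
    expect_equal(pk$baseline_pa, pk0$baseline_pa + off, tolerance = 1e-9)
  }
})

test_that("peaks are reported as non-negative magnitudes for either sign convention", {
  tr <- simulate_trace(step_protocol(-30), channel_params(), membrane_model())
  pk_neg <- measure_peaks(tr, inward_negative = TRUE)
  tr_mag <- tr
  tr_mag$current_pa <- -tr_mag$current_pa
  pk_pos <- measure_peaks(tr_mag, inward_negative = FALSE)
  expect_equal(pk_neg$peak_on_pa, pk_pos$peak_on_pa, tolerance = 1e-12)
  expect_gte(pk_neg$peak_on_pa, 0)
})

test_that("window validation and NaN detection raise errors", {
  tr <- simulate_trace(step_protocol(-30), channel_params(), membrane_model())
  expect_error(measure_peaks(tr, step_window = c(5, 6)), "window")
  expect_error(measure_peaks(tr, baseline_window = c(0.3, 0.2)), "window")
  expect_error(measure_peaks(tr, baseline_window = c(0.2, 0.35)), "precede")
  tr$current_pa[10] <- NA
  expect_error(measure_peaks(tr), "NA")
})

test_that("QC applies the configuration-dependent thresholds", {
  expect_true(apply_qc(2, 60, "cell_attached", "negative")$passed)
  expect_false(apply_qc(2, 40, "cell_attached", "negative")$passed)
  q <- apply_qc(0.5, 120, "cell_attached", "negative")
  expect_false(q$passed)
  expect_match(q$reason, "seal")
  # 20 pA threshold for all other configurations
  expect_true(apply_qc(1.5, 25, "outside_out", "positive")$passed)
  expect_true(apply_qc(1.5, 25, "cell_attached", "positive")$passed)
  expect_false(apply_qc(1.5, 25, "inside_out", "negative")$passed)
  expect_error(apply_qc(NA, 60, "cell_attached"), "required")
})

test_that("raising QC thresholds never converts failure into a pass", {
  cases <- expand.grid(seal = c(0.5, 1, 2), cur = c(10, 30, 60))
  for (i in seq_len(nrow(cases))) {
    base <- apply_qc(cases$seal[i], cases$cur[i], "cell_attached", "negative")
    strict <- apply_qc(cases$seal[i], cases$cur[i], "cell_attached", "negative",
                       min_seal_gohm = 2,
                       current_thresholds = c(strict = 80, lenient = 40))
    if (!base$passed) expect_false(strict$passed)
  }
})
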