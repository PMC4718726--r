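test_that("fit_boltzmann recovers noise-free parameters exactly", {
  # generative parameters of a saturating normalized tension curve
  x <- seq(0, 8, by = 0.5)
  y <- boltzmann(x, 0.99, 2.7, 0.8)
  f <- fit_boltzmann(x, y)
  expect_equal(f$i_max, 0.99, tolerance = 1e-6)
  expect_equal(f$x50, 2.7, tolerance = 1e-6)
  expect_equal(f$k, 0.8, tolerance = 1e-6)
  # midpoint identity: fitted curve passes through i_max/2 at x50
  expect_equal(boltzmann(f$x50, f$i_max, f$x50, f$k), f$i_max / 2)
  # degenerate and short inputs
  expect_error(fit_boltzmann(x, rep(1, length(x))), "degenerate")
  expect_error(fit_boltzmann(1:3, 1:3), "at least 4")
})

test_that("SD weights equal to each other reproduce the unweighted fit", {
  x <- seq(0, 10, by = 1)
  y <- boltzmann(x, 1, 4.7, 1.2)
  f1 <- fit_boltzmann(x, y)
  f2 <- fit_boltzmann(x, y, sd = rep(0.05, length(x)))
  expect_equal(f1$x50, f2$x50, tolerance = 1e-8)
  expect_equal(f1$k, f2$k, tolerance = 1e-8)
})

test_that("inflating one bin's SD moves the fit toward the remaining bins", {
  # constructed case: one outlier bin pulled off the curve
  x <- c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5)
  y <- boltzmann(x, 1, 2.7, 0.8)
  y[3] <- y[3] + 0.3
  sd0 <- rep(0.05, 7)
  f_tight <- fit_boltzmann(x, y, sd = sd0)
  sd1 <- sd0; sd1[3] <- 0.5
  f_loose <- fit_boltzmann(x, y, sd = sd1)
  clean_rss <- function(f) sum((boltzmann(x[-3], f$i_max, f$x50, f$k) - y[-3])^2)
  expect_lt(clean_rss(f_loose), clean_rss(f_tight))
})

test_that("pressure-domain cell fits report signed midpoints", {
  dp <- seq(0, -50, by = -5)
  y <- boltzmann(abs(dp), 200, 16.7, 3)
  f <- fit_cell_pressure(dp, y)
  expect_equal(f$p50_signed, -16.7, tolerance = 1e-5)
  expect_identical(f$domain, "pressure")
  expect_identical(f$units, "mmHg")
})

test_that("normalize_responses handles both modes", {
  resp <- data.frame(cell_id = rep(c("a", "b"), each = 11),
                     dp_mmhg = rep(seq(0, -50, by = -5), 2))
  resp$peak_pa <- ifelse(resp$cell_id == "a",
                         boltzmann(abs(resp$dp_mmhg), 200, 15, 3),
                         boltzmann(abs(resp$dp_mmhg), 120, 25, 4))
  nm <- normalize_responses(resp, "max_response")
  expect_equal(as.numeric(tapply(nm$norm_current, nm$cell_id, max)), c(1, 1))
  np <- normalize_responses(resp, "plateau_of_fit")
  fits <- attr(np, "cell_fits")
  expect_equal(fits[["a"]]$i_max, 200, tolerance = 1e-4)
  # response / fitted plateau: 100 pA in a 200 pA cell -> 0.5
  expect_equal(np$norm_current[np$cell_id == "a"],
               resp$peak_pa[resp$cell_id == "a"] / 200, tolerance = 1e-4)
})

test_that("plateau mode drops cells whose pressure fit fails, with a warning", {
  good <- data.frame(cell_id = "good", dp_mmhg = seq(0, -50, by = -5))
  good$peak_pa <- boltzmann(abs(good$dp_mmhg), 150, 18, 3)
  bad <- data.frame(cell_id = "bad", dp_mmhg = seq(0, -10, by = -5),
                    peak_pa = c(1, 1, 1))
  expect_warning(nm <- normalize_responses(rbind(good, bad), "plateau_of_fit"),
                 "excluded")
  expect_identical(unique(nm$cell_id), "good")
})

test_that("pool_and_bin uses zero-anchored left-closed bins", {
  h <- pool_and_bin(c(0.2, 0.8), c(0.5, 0.7), bin_width = 1)
  expect_equal(nrow(h), 1L)
  expect_equal(h$bin_lo, 0)
  expect_equal(h$center, 0.5)
  expect_equal(h$n, 2L)
  expect_equal(h$mean, 0.6)
  # boundary value 1.0 falls in [1, 2)
  h2 <- pool_and_bin(c(0.5, 1.0), c(1, 1), bin_width = 1)
  expect_equal(h2$bin_lo, c(0, 1))
  # identical values within a bin: sem exactly 0
  h3 <- pool_and_bin(c(0.1, 0.2, 3.3), c(0.4, 0.4, 1), bin_width = 1)
  expect_equal(h3$sem[1], 0)
  # singleton bins inherit the median multi-member SD
  expect_equal(h3$sd[2], h3$sd[1])
})

test_that("fit_tension_curve recovers binned generative parameters", {
  set.seed(5)
  tension <- runif(400, 0, 9)
  y <- boltzmann(tension, 0.99, 2.7, 0.8) + rnorm(400, 0, 0.04)
  h <- pool_and_bin(tension, y, 1)
  f <- fit_tension_curve(h)
  expect_identical(f$domain, "tension")
  expect_identical(f$units, "mN/m")
  expect_true(f$weighted)
  expect_equal(f$x50, 2.7, tolerance = 0.1)
  expect_equal(f$k, 0.8, tolerance = 0.15)
  expect_error(fit_tension_curve(pool_and_bin(c(0.1, 1.1), c(0, 1), 1)),
               "at least 4")
})

test_that("fit_recovery recovers noise-free parameters exactly", {
  t <- c(0.3, 0.5, 1, 2, 3, 5, 7, 10)
  y <- 0.82 - 0.49 * exp(-(t - 0.3) / 2.4)
  f <- fit_recovery(t, y)
  expect_equal(f$i_max, 0.82, tolerance = 1e-6)
  expect_equal(f$A, 0.49, tolerance = 1e-6)
  expect_equal(f$tau, 2.4, tolerance = 1e-6)
  expect_identical(f$t0, 0.3)
  # asymptote: fitted curve tends to i_max
  expect_equal(f$i_max - f$A * exp(-(1e6 - f$t0) / f$tau), f$i_max)
  # monotone non-decreasing over the fitted range
  tt <- seq(0.3, 10, length.out = 50)
  expect_true(all(diff(f$i_max - f$A * exp(-(tt - f$t0) / f$tau)) >= 0))
  # decreasing data is a sign error, not a silent fit
  expect_error(fit_recovery(t, rev(y)), "decrease")
  expect_error(fit_recovery(c(1, 2, 2, 1), c(1, 2, 3, 4)), "distinct")
})

test_that("free-t0 recovery fit also reproduces generative parameters", {
  t <- c(0.3, 0.5, 1, 1.5, 2, 3, 4, 5, 7, 10)
  y <- 0.82 - 0.49 * exp(-(t - 0.3) / 2.4)
  f <- fit_recovery(t, y, free_t0 = TRUE)
  expect_equal(f$tau, 2.4, tolerance = 1e-4)
  expect_equal(f$i_max, 0.82, tolerance = 1e-5)
})

test_that("T50 recovery is unbiased at the standard cohort scale", {
  # scaled-down replicate study (60 of the nominal 200 replicates, for
  # test-suite runtime); median absolute error bound unchanged
  errs <- vapply(1:60, function(s) {
    resp <- simulate_response_set(simulation_config(seed = s), "cell_attached")
    res <- analyze_tension_cohort(resp, normalize = "plateau_of_fit")
    res$fit$x50 - 2.7
  }, 0)
  expect_lt(stats::median(abs(errs)), 0.15)
})

test_that("plateau-normalized pooled fits saturate near 1", {
  for (s in c(2, 12)) {
    resp <- simulate_response_set(simulation_config(seed = s), "cell_attached")
    res <- analyze_tension_cohort(resp, normalize = "plateau_of_fit")
    expect_gt(res$fit$i_max, 0.7)
    expect_lt(res$fit$i_max, 1.1)
  }
})

test_that("bootstrap CI brackets the point estimate", {
  resp <- simulate_response_set(simulation_config(seed = 8), "cell_attached")
  res <- analyze_tension_cohort(resp, normalize = "plateau_of_fit")
  ci <- boot_tension_ci(res$responses$tension_mN_per_m,
                        res$responses$norm_current, n_boot = 60, seed = 2)
  expect_lt(ci["x50", "lo"], res$fit$x50)
  expect_gt(ci["x50", "hi"], res$fit$x50)
})
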