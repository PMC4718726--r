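test_that("laplace_tension converts units correctly and symmetrically", {
  # dimensional analysis: T[mN/m] = R[um] * |dp|[mmHg] * 133.322e-3 / 2
  expect_equal(laplace_tension(2.87, -20), 2.87 * 20 * 133.322e-3 / 2,
               tolerance = 1e-12)
  expect_equal(laplace_tension(2.87, -20), 3.83, tolerance = 2e-3)
  # unit-sanity anchor
  expect_equal(laplace_tension(1, 15), 1.0, tolerance = 0.01)
  # symmetry in the sign of dp
  expect_identical(laplace_tension(2.87, 20), laplace_tension(2.87, -20))
  # zero pressure and flat membranes carry zero tension
  expect_identical(laplace_tension(2.87, 0), 0)
  expect_identical(laplace_tension(5, -30, flat = TRUE), 0)
  expect_identical(laplace_tension(Inf, -30), 0)
  expect_error(laplace_tension(-1, 10), "radius")
})

test_that("laplace_tension is exactly linear in radius and |dp|", {
  r <- c(0.5, 1, 2, 4, 8)
  dp <- c(-40, -20, -5, 5, 20)
  for (a in c(2, 7)) {
    expect_equal(laplace_tension(a * r, dp), a * laplace_tension(r, dp))
    expect_equal(laplace_tension(r, a * dp), a * laplace_tension(r, dp))
  }
})

test_that("inverse_radius follows the sign convention and flat flag", {
  pts <- arc_points(20, 2)
  fit_convex <- fit_circle(pts, orient_point = c(100, 0))
  expect_equal(inverse_radius(fit_convex), 0.5, tolerance = 1e-9)
  fit_concave <- fit_circle(pts, orient_point = c(0, 0))
  expect_equal(inverse_radius(fit_concave), -0.5, tolerance = 1e-9)
  flat_fit <- fit_circle(cbind(0:10, rep(1, 11)))
  expect_true(flat_fit$flat)
  expect_identical(inverse_radius(flat_fit), 0)
})

test_that("simulated response tables are Laplace-consistent to 1e-12", {
  resp <- simulate_response_set(simulation_config(seed = 3), "cell_attached")
  t_re <- laplace_tension(resp$radius_true_um, resp$dp_mmhg,
                          flat = !is.finite(resp$radius_true_um))
  expect_equal(t_re, resp$tension_true, tolerance = 1e-12)
})

test_that("tension_table joins and honors the drop_flat switch", {
  circles <- data.frame(cell_id = "c1", sweep_id = 1:3,
                        radius_um = c(2, Inf, 4), flat = c(FALSE, TRUE, FALSE))
  pressures <- data.frame(cell_id = "c1", sweep_id = 1:3,
                          dp_mmhg = c(-10, -10, 0))
  tt <- tension_table(circles, pressures)
  expect_equal(nrow(tt), 3L)
  expect_equal(tt$tension_mN_per_m[tt$sweep_id == 2], 0)
  expect_equal(tt$tension_mN_per_m[tt$sweep_id == 3], 0)
  expect_equal(nrow(tension_table(circles, pressures, drop_flat = TRUE)), 2L)
})
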