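test_that("fit_circle solves the circumscribed-circle case exactly", {
  f <- fit_circle(rbind(c(0, 1), c(1, 0), c(0, -1)))
  expect_equal(f$center, c(0, 0), tolerance = 1e-9)
  expect_equal(f$radius, 1, tolerance = 1e-9)
  expect_error(fit_circle(rbind(c(0, 1), c(1, 0))), "at least 3")
})

test_that("fit_circle reconstructs a noise-free arc", {
  pts <- arc_points(20, 2.87, center = c(5, -3), theta = c(0.4, 2.2))
  f <- fit_circle(pts)
  expect_equal(f$radius, 2.87, tolerance = 1e-9)
  expect_lt(f$rms_um, 1e-9)
  expect_equal(abs(f$signed_curvature), 1 / f$radius)
})

test_that("fit_circle matches the exhaustive grid-search oracle", {
  cases <- list(
    list(n = 50, r = 5, jit = 0.05, seed = 2),
    list(n = 30, r = 2, jit = 0.1, seed = 3),
    list(n = 60, r = 8, jit = 0.02, seed = 4))
  for (cs in cases) {
    pts <- arc_points(cs$n, cs$r, jitter_sd = cs$jit, seed = cs$seed)
    f <- fit_circle(pts)
    oracle <- grid_circle_oracle(pts)
    ss_fit <- circle_ss(pts, f$center, f$radius)
    # the refined fit must never be worse than the 0.01-um grid optimum,
    # and must agree with it to within grid resolution
    expect_lte(ss_fit, oracle$ss + 1e-12)
    expect_equal(f$radius, oracle$radius, tolerance = 0.02)
    expect_equal(f$center, oracle$center, tolerance = 0.02)
  }
})

test_that("fit_circle is equivariant under rotation and translation", {
  pts <- arc_points(40, 3.2, jitter_sd = 0.03, seed = 7)
  f0 <- fit_circle(pts)
  for (i in 1:5) {
    set.seed(i)
    th <- runif(1, 0, 2 * pi)
    shift <- runif(2, -10, 10)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    f1 <- fit_circle(sweep(pts %*% t(Rm), 2, -shift))
    expect_equal(f1$radius, f0$radius, tolerance = 1e-9)
    expect_equal(f1$center, as.numeric(Rm %*% f0$center + shift), tolerance = 1e-8)
  }
})

test_that("near-collinear profiles are reported flat, not as huge circles", {
  f <- fit_circle(cbind(seq(0, 5, by = 0.5), rnorm(11, 0, 1e-7)))
  expect_true(f$flat)
  expect_identical(f$radius, Inf)
  expect_identical(f$signed_curvature, 0)
})

test_that("rendering is deterministic and validates geometry", {
  g <- pipette_geometry()
  i1 <- render_patch_image(g, 2.87, noise_sd = 3, seed = 9)
  i2 <- render_patch_image(g, 2.87, noise_sd = 3, seed = 9)
  expect_identical(i1$intensities, i2$intensities)
  i3 <- render_patch_image(g, 2.87, noise_sd = 3, seed = 10)
  expect_false(identical(i1$intensities, i3$intensities))
  # dome smaller than the pipette opening cannot exist
  expect_error(render_patch_image(g, 1.0), "radius")
  # explicit field of view too small for the arc
  expect_error(render_patch_image(g, 2.87, image_shape = c(60, 60)),
               "does not fit")
})

test_that("estimate_walls recovers the configured geometry within 1 degree", {
  g <- pipette_geometry(half_angle = 10, axis_angle = 15)
  img <- render_patch_image(g, 2.87, noise_sd = 2, seed = 4)
  walls <- estimate_walls(img)
  expect_equal(attr(walls, "half_angle_deg"), 10, tolerance = 1)
  # bisector within 0.5 degree of the configured axis
  expect_equal(attr(walls, "axis_angle_deg"), 15, tolerance = 0.5)
  # no walls at all
  expect_error(estimate_walls(patch_image(matrix(180, 80, 80), 1 / 61.5)),
               "line features")
})

test_that("detect_membrane localizes a noise-free arc to sub-half-pixel", {
  img <- render_patch_image(pipette_geometry(), 2.87, noise_sd = 0)
  prof <- detect_membrane(img)
  expect_gt(nrow(prof), 50)
  expect_lt(max(profile_circle_err_px(prof, img)), 0.5)
  # profile points respect the wall-exclusion margin
  walls <- attr(prof, "walls")
  dw <- pmin(
    abs((prof$x_um - walls[[1]]$point[1]) * -walls[[1]]$dir[2] +
        (prof$y_um - walls[[1]]$point[2]) * walls[[1]]$dir[1]),
    abs((prof$x_um - walls[[2]]$point[1]) * -walls[[2]]$dir[2] +
        (prof$y_um - walls[[2]]$point[2]) * walls[[2]]$dir[1]))
  expect_gt(min(dw) / img$pixel_size, 5)
})

test_that("smoothing window barely matters on a noise-free image", {
  img <- render_patch_image(pipette_geometry(), 2.87, noise_sd = 0)
  p9 <- detect_membrane(img, window = 9)
  p1 <- detect_membrane(img, window = 1)
  common <- intersect(round(p1$t_um, 6), round(p9$t_um, 6))
  i1 <- match(common, round(p1$t_um, 6))
  i9 <- match(common, round(p9$t_um, 6))
  expect_lt(max(abs(p1$s_um[i1] - p9$s_um[i9])) / img$pixel_size, 0.3)
})

test_that("uniform images raise a detection failure", {
  expect_error(detect_membrane(patch_image(matrix(100, 60, 60), 1 / 61.5)),
               "detection failure|line features")
})

test_that("flat membranes come back with curvature zero", {
  img <- render_patch_image(pipette_geometry(), Inf, noise_sd = 1, seed = 2)
  f <- measure_patch_radius(img)
  expect_true(f$flat)
  expect_identical(f$signed_curvature, 0)
})

test_that("concave domes get negative signed curvature", {
  img <- render_patch_image(pipette_geometry(), -4, noise_sd = 1, seed = 3)
  f <- measure_patch_radius(img)
  expect_false(f$flat)
  expect_lt(f$signed_curvature, 0)
  expect_equal(f$radius, 4, tolerance = 0.05)
})

test_that("radius recovery stays within 2% and degrades monotonically with noise", {
  # scaled-down version of the 100-image screen (12 radii x 2 noise levels)
  radii <- exp(seq(log(1), log(10), length.out = 12))
  errs <- sapply(seq_along(radii), function(i) {
    r <- radii[i]
    g <- pipette_geometry(tip_inner_radius = 0.55 * r, half_angle = 10)
    vapply(c(low = 1, high = 12), function(nz) {
      img <- render_patch_image(g, r, noise_sd = nz, seed = 100 + i,
                                halfwidth = 0.8 * r)
      f <- measure_patch_radius(img)
      abs(f$radius - r) / r
    }, 0)
  })
  expect_lt(stats::median(errs["low", ]), 0.02)
  expect_lt(stats::median(errs["high", ]), 0.02)
  # monotone degradation in expectation over the image set
  expect_lte(mean(errs["low", ]), mean(errs["high", ]))
})
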