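test_that("zero-noise profiles equal the forward model exactly", {
  tru <- recovery_truth()
  g <- recovery_grids()
  prof <- generate_profile_data(tru, g$depth, g$time, noise_sigma = 0)
  # reference: direct simulation + projection on the same grids
  tr <- simulate_staining(tru$kinetics, tru$geometry, tru$growth,
                          times = g$time, n_nodes = tru$sim_nodes)
  ih <- project_intensity(tr)
  pos <- g$depth >= 0
  ref <- apply(ih, 2, function(v)
    stats::approx(tr$x, v, xout = g$depth[pos])$y)
  expect_equal(prof$values[pos, ], unname(ref))
  u_sol <- tru$kinetics$F_I2C * tru$kinetics$C0 * tru$geometry$D
  expect_true(all(prof$values[!pos, ] == u_sol))
})

test_that("profile generation is seed-deterministic and noise is unbiased", {
  tru <- recovery_truth(noise_sigma = 0.01, seed = 5L)
  depth <- seq(-0.1, 0.5, by = 0.05); tt <- seq(0, 200, 50)
  p1 <- generate_profile_data(tru, depth, tt)
  p2 <- generate_profile_data(tru, depth, tt)
  expect_identical(p1$values, p2$values)
  p0 <- generate_profile_data(tru, depth, tt, noise_sigma = 0)
  reps <- sapply(1:50, function(s)
    generate_profile_data(tru, depth, tt, seed = 1000 + s)$values)
  m <- matrix(rowMeans(reps), length(depth))
  expect_lt(max(abs(m - p0$values)), 3 * 0.01 / sqrt(50) * 4)
  expect_error(generate_profile_data(tru, c(0, 0, 1), tt), "invalid-grid")
})

test_that("stack generation is deterministic and geometry-checked", {
  tru <- synth_ground_truth(geometry = geometry_model(),
                            growth = growth_model(), noise_sigma = 5,
                            seed = 9L)
  acq <- acquisition_spec(n_frames = 6)
  s1 <- generate_projection_stack(tru, acq)
  s2 <- generate_projection_stack(tru, acq)
  expect_identical(s1$stack$frames, s2$stack$frames)
  # punch must fit the image
  small <- acquisition_spec(n_frames = 6, image_shape = c(160, 120))
  expect_error(generate_projection_stack(tru, small), "geometry-overflow")
})

test_that("the surface row follows the growth curve rounded to pixels", {
  tru <- synth_ground_truth(geometry = geometry_model(),
                            growth = growth_model(), noise_sigma = 0,
                            seed = 2L)
  acq <- acquisition_spec(n_frames = 10)
  syn <- generate_projection_stack(tru, acq)
  g <- growth_percent(tru$growth, syn$render$times)
  expected <- syn$render$bottom_row -
    round(tru$sample_height * (1 + g / 100) / acq$pixel_size)
  expect_equal(syn$render$surface_rows, expected)
})

test_that("concentration series is linear through the calibration", {
  acq <- acquisition_spec(n_frames = 5, image_shape = c(40, 40))
  ser <- generate_concentration_series(c(1, 2, 3), acq, noise_sigma = 5,
                                       seed = 2)
  mu <- sapply(ser, function(s)
    mean(acq$detector_full_scale - simplify2array(s$frames)))
  r <- stats::cor(c(1, 2, 3), mu)
  expect_gt(r, 0.999)   # must not do worse than the measured r = 0.99
  # zero concentration sits at the calibration baseline within noise
  ser0 <- generate_concentration_series(0, acq, noise_sigma = 5, seed = 2)
  cal <- detector_calibration()
  mu0 <- mean(acq$detector_full_scale - simplify2array(ser0[[1]]$frames))
  expect_equal(mu0, cal$offset, tolerance = 1e-3)
  expect_error(generate_concentration_series(c(-1, 2), acq),
               "domain error")
})

test_that("detector calibration anchors the solution level", {
  cal <- detector_calibration()
  p <- standardization_params()
  expect_equal(cal$u_sol, (10 * (1 + p$a) - 9) / (10 * (1 + p$a)))
  expect_equal(solution_C0() * 25 * 214.6308, cal$u_sol)
})
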