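test_that("absorbance conversion and stage checking work", {
  p <- intensity_profile(c(-0.1, 0, 0.1), c(0, 10),
                         matrix(c(10000, 3580, 7000, 10000, 3580, 7000),
                                3, 2), stage = "raw_w")
  u <- to_absorbance(p)
  expect_equal(u$values[1, 1], 0)
  expect_equal(u$values[2, 1], 6420)
  expect_error(to_absorbance(u), "stage error")
  # order reversal: decreasing w means increasing u
  expect_true(all(diff(p$values[, 1]) * diff(u$values[, 1]) <= 0))
})

test_that("baseline correction implements u - b(t) - median(b)", {
  depth <- seq(-0.25, 0.2, by = 0.025)
  tt <- c(0, 10, 20)
  # constant absorbance c: b(t) = c, median = c, so u_b = -c
  u <- intensity_profile(depth, tt, matrix(1234, length(depth), 3),
                         stage = "absorbance_u")
  ub <- baseline_correct(u)
  expect_true(all(ub$values == -1234))
  # zero baseline leaves the profile untouched
  vals <- matrix(0, length(depth), 3)
  vals[depth > 0, ] <- 55
  u2 <- intensity_profile(depth, tt, vals, stage = "absorbance_u")
  expect_equal(baseline_correct(u2)$values, vals)
  # additive per-time drift is removed up to a constant in the solution
  drift <- c(-30, 0, 40)
  u3 <- intensity_profile(depth, tt, sweep(vals, 2, -drift),
                          stage = "absorbance_u")
  ub3 <- baseline_correct(u3)
  sol <- depth < -0.05
  expect_lt(max(apply(ub3$values[sol, ], 1, function(r) diff(range(r)))),
            1e-10)
  expect_error(baseline_correct(u,
    standardization_params(baseline_window = c(-0.9, -0.8))), "window error")
})

test_that("standardization reproduces the hand-computed affine map", {
  # constructed so that the mean over the [-0.2, 0] window is exactly 1000
  depth <- seq(-0.2, 0.1, by = 0.02)
  vals <- matrix(1000, length(depth), 2)
  vals[depth > 0, ] <- 2000
  ub <- intensity_profile(depth, c(0, 10), vals,
                          stage = "baseline_corrected_ub")
  uh <- suppressWarnings(standardize_profile(ub))
  s <- attr(uh, "standardization")
  expect_equal(s$bbar, 1000)
  expect_equal(s$u_min, 397.778, tolerance = 1e-5)
  expect_equal(s$u_ref, -3320.88, tolerance = 1e-5)
  expect_equal(s$u_norm, 9740.88, tolerance = 1e-5)
  expect_equal(uh$values[depth > 0, 1][1], 0.54624, tolerance = 1e-4)
  # affine anchor points: u_b = u_ref -> 0, u_b = u_ref + u_norm -> 1
  expect_equal((s$u_ref - s$u_ref) / s$u_norm, 0)
  expect_equal((s$u_ref + s$u_norm - s$u_ref) / s$u_norm, 1)
})

test_that("the preprocessing chain is affine in the input intensities", {
  # scaling all deviations from the baseline level by k scales the
  # standardized deviations from the solution level by k
  depth <- seq(-0.25, 0.5, by = 0.025)
  tt <- c(0, 10, 20)
  base <- 6000
  dev <- outer(pmax(depth, 0), tt / 20 + 0.5)  # arbitrary structure
  chain <- function(k) {
    w <- matrix(base, length(depth), 3) - k * 1000 * dev
    p <- intensity_profile(depth, tt, w, stage = "raw_w")
    suppressWarnings(
      standardize_profile(baseline_correct(to_absorbance(p))))$values
  }
  u1 <- chain(1); u2 <- chain(2)
  sol_level1 <- mean(u1[depth < -0.05, ])
  sol_level2 <- mean(u2[depth < -0.05, ])
  expect_equal(u2 - sol_level2, 2 * (u1 - sol_level1), tolerance = 1e-9)
})

test_that("registration recovers integer, zero and subpixel shifts", {
  tr <- stainkinetics:::.translate
  set.seed(11)
  base <- matrix(rnorm(80 * 90), 80, 90) +
    outer(seq(0, 2, length.out = 80), seq(0, 1, length.out = 90))
  st <- projection_stack(list(base, tr(base, -3, 2), base,
                              tr(base, -0.4, 0.4)),
                         c(0, 1, 2, 3), 0.02)
  reg <- register_stack(st)
  expect_equal(reg$shifts[2, ], c(row = 3, col = -2), tolerance = 0.06)
  expect_equal(reg$shifts[3, ], c(row = 0, col = 0), tolerance = 1e-6)
  expect_lt(max(abs(reg$shifts[4, ] - c(0.4, -0.4))), 0.25)
  flat <- projection_stack(list(base, matrix(5, 80, 90)), c(0, 1), 0.02)
  expect_error(register_stack(flat), "registration-undefined")
})

test_that("flat-field correction removes a known quadratic bias", {
  nr <- 60; nc <- 70
  yn <- seq(-1, 1, length.out = nr); xn <- seq(-1, 1, length.out = nc)
  Z <- outer(yn, xn, function(y, x) -0.1 * x^2 - 0.15 * y^2 + 0.02 * x)
  Z <- Z - max(Z)
  flat <- matrix(8000, nr, nc)
  frames <- replicate(6, flat * exp(Z), simplify = FALSE)
  st <- projection_stack(frames, 0:5, 0.02)
  corr <- flatfield_correct(st)
  expect_lt(max(abs(corr$frames[[1]] - flat) / flat), 0.01)
  # near-idempotence: a second pass changes pixels by < 0.1%
  corr2 <- flatfield_correct(corr)
  expect_lt(max(abs(corr2$frames[[1]] - corr$frames[[1]]) /
                  corr$frames[[1]]), 0.001)
  # spatially constant stack is untouched
  stc <- projection_stack(replicate(6, flat, simplify = FALSE), 0:5, 0.02)
  expect_equal(flatfield_correct(stc)$frames[[3]], flat, tolerance = 1e-10)
  expect_error(flatfield_correct(projection_stack(frames[1:4], 0:3, 0.02)),
               ">= 5 frames")
  frames_bad <- frames
  for (k in 2:5) frames_bad[[k]][5, 7] <- -1
  expect_error(flatfield_correct(projection_stack(frames_bad, 0:5, 0.02)),
               "log-domain")
})

test_that("profile extraction samples the cross-section correctly", {
  st <- projection_stack(replicate(3, matrix(7000, 60, 60),
                                   simplify = FALSE), c(0, 5, 10), 0.02)
  cs <- cross_section(origin = c(30, 30), half_width = 5,
                      depth_extent = 0.3, solution_extent = 0.2)
  p <- extract_profile(st, cs)
  expect_true(all(p$values == 7000))
  expect_equal(p$stage, "raw_w")
  expect_equal(range(p$depth), c(-0.2, 0.3))
  expect_error(cross_section(origin = c(30, 30), half_width = 0),
               "half_width")
  cs_oob <- cross_section(origin = c(30, 58), depth_extent = 0.3,
                          solution_extent = 0.2)
  expect_error(extract_profile(st, cs_oob), "geometry error")
})

test_that("height tracking is exact on a static stack", {
  nr <- 60
  frame <- matrix(9000, nr, 40)
  frame[30:nr, ] <- 4000   # sample below a sharp surface at row 30
  st <- projection_stack(replicate(8, frame, simplify = FALSE),
                         seq(0, 70, 10), 0.02)
  th <- track_height(st, search_rows = c(5, 55), band_cols = c(10, 30))
  expect_true(all(th$percent_change == 0))
})
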