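test_that("initial state follows the stated conditions", {
  kp <- kinetic_params()
  gm <- geometry_model()
  x <- seq(0, gm$L, length.out = 301)
  st <- initial_state(kp, gm, x)
  expect_true(all(st[, "b"] == 0))
  expect_true(all(st[-1, "f"] == 0))
  expect_equal(unname(st[1, "f"]), kp$C0 * gm$R)
  expect_equal(unname(st[1, "o"]), kp$C0 * (gm$D - gm$R))   # = 21 * C0
  deep <- which(x >= gm$H)
  expect_equal(unname(st[deep, "o"]),
               rep(kp$C0 * (gm$D - gm$R), length(deep)))
  # quadrature cross-check: integral of s equals S0 * integral of d
  w <- rep(diff(x)[1], length(x)); w[c(1, length(x))] <- w[1] / 2
  int_s <- sum(w * st[, "s"])
  int_d <- sum(w * thickness(x, gm))
  # surface node carries the boundary value s = 0 instead of S0*d(0)=0,
  # so the two quadratures agree exactly
  expect_equal(int_s, kp$S0 * int_d, tolerance = 1e-12)
})

test_that("pure diffusion matches the semi-infinite erfc solution", {
  kp <- kinetic_params(De = 1e-3, kon = 0, kunmask = 0, S0 = 0, M0 = 0)
  gm <- geometry_model(R = 4, H = 0, D = 25, L = 3)   # flat geometry
  tr <- simulate_staining(kp, gm, NULL, times = c(0, 600), n_nodes = 301)
  num <- tr$f[, 2] / (kp$C0 * gm$R)
  ana <- erfc_(tr$x / (2 * sqrt(kp$De * 600)))
  expect_lt(max(abs(num - ana)[tr$x <= 2]), 1e-2)
  # spot value from the closed form
  expect_equal(erfc_(0.775 / (2 * sqrt(1e-3 * 600))), 0.4795,
               tolerance = 2e-3)
})

test_that("reaction stoichiometry and frozen pools behave as stated", {
  kp <- kinetic_params(De = 5e-4, kon = 1e3, kunmask = 30,
                       S0 = 3e-4, M0 = 1e-4)
  gm <- geometry_model()
  tr <- simulate_staining(kp, gm, NULL, times = seq(0, 400, 100),
                          n_nodes = 201)
  mb <- mass_balance(tr)
  expect_lt(mb$max_rel_drift_smb, 1e-8)     # s+m+b pointwise invariant, v=0

  tr_nob <- simulate_staining(kinetic_params(De = 5e-4, kon = 0,
                                             kunmask = 30, S0 = 3e-4,
                                             M0 = 1e-4),
                              gm, NULL, times = c(0, 200), n_nodes = 201)
  expect_true(all(tr_nob$b == 0))           # no binding without kon

  tr_noum <- simulate_staining(kinetic_params(De = 5e-4, kon = 1e3,
                                              kunmask = 0, S0 = 3e-4,
                                              M0 = 1e-4),
                               gm, NULL, times = c(0, 200), n_nodes = 201)
  expect_equal(tr_noum$m[, 2], tr_noum$m[, 1], tolerance = 1e-10)
})

test_that("closed system conserves total free plus bound osmium", {
  kp <- kinetic_params(De = 5e-4, kon = 1e3, kunmask = 30,
                       S0 = 3e-4, M0 = 1e-4)
  gm <- geometry_model()
  x <- seq(0, gm$L, length.out = 301)
  f0 <- 1e-4 * exp(-((x - 1) / 0.3)^2)
  tr <- simulate_staining(kp, gm, NULL, times = seq(0, 600, 100),
                          n_nodes = 301, closed = TRUE, f0 = f0,
                          rtol = 1e-8, atol = 1e-12)
  expect_lt(mass_balance(tr)$rel_drift_fb, 1e-6)
})

test_that("projected intensity is linear and matches the solution column", {
  kp <- kinetic_params()
  gm <- geometry_model()
  tr <- simulate_staining(kp, gm, NULL, times = c(0, 60), n_nodes = 151)
  ih <- project_intensity(tr)
  # at t = 0 the surface node carries o + f = C0 (D - R) + C0 R = C0 D
  expect_equal(ih[1, 1], kp$F_I2C * kp$C0 * gm$D, tolerance = 1e-12)
  tr2 <- tr
  tr2$f <- 2 * tr$f; tr2$b <- 2 * tr$b; tr2$o <- 2 * tr$o
  expect_equal(project_intensity(tr2), 2 * ih)
  tr0 <- tr
  tr0$f[] <- 0; tr0$b[] <- 0; tr0$o[] <- 0
  expect_true(all(project_intensity(tr0) == 0))
})

test_that("grid refinement changes the projected intensity by little", {
  kp <- kinetic_params()
  gm <- geometry_model(R = 4, H = 0.4, D = 25, L = 1.5)
  gr <- growth_model()
  times <- seq(0, 600, 120)
  co <- simulate_staining(kp, gm, gr, times = times, n_nodes = 151)
  fi <- simulate_staining(kp, gm, gr, times = times, n_nodes = 301)
  xq <- seq(0.1, 0.7, by = 0.02)
  iho <- apply(project_intensity(co), 2, function(v)
    stats::approx(co$x, v, xout = xq)$y)
  ihf <- apply(project_intensity(fi), 2, function(v)
    stats::approx(fi$x, v, xout = xq)$y)
  expect_lt(max(abs(iho - ihf) / abs(ihf)), 0.005)
})

test_that("simulation input contracts are enforced", {
  kp <- kinetic_params()
  gm <- geometry_model()
  expect_error(simulate_staining(kp, gm, NULL, times = c(10, 20)),
               "start at 0")
  expect_error(simulate_staining(kp, gm, NULL, times = c(0, 0, 10)),
               "strictly increasing")
  expect_error(kinetic_params(De = -1), "non-negative")
})
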