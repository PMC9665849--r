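test_that("projected thickness follows the curvature-circle chord", {
  gm <- geometry_model(R = 4, H = 0.5)
  expect_equal(thickness(0, gm), 0)
  expect_equal(thickness(gm$H, gm), gm$R)          # chord at the cap base
  expect_equal(thickness(2, gm), gm$R)             # clamped beyond the cap
  expect_equal(thickness(0.25, gm), 2.87228, tolerance = 1e-5)
  expect_error(thickness(-0.1, gm), "x < 0")
})

test_that("curvature radius matches its closed form and limits", {
  expect_equal(curvature_radius(geometry_model(R = 4, H = 0.5)), 4.25)
  # hemispherical cap: radius R/2
  expect_equal(curvature_radius(geometry_model(R = 3, H = 1.5, L = 2)), 1.5)
  expect_error(curvature_radius(geometry_model(R = 4, H = 0)),
               "degenerate")
})

test_that("thickness agrees with brute-force circle intersection", {
  # independent construction: the circle through the apex (0, 0) and the
  # rim (H, +-R/2) with centre on the depth axis; chord via root finding
  set.seed(42)
  for (i in 1:200) {
    R <- runif(1, 1, 8); H <- runif(1, 0.05, R / 2)
    x <- runif(1, 1e-4, H * 0.999)
    rc <- (H^2 + R^2 / 4) / (2 * H)   # centre depth = rc below the apex...
    # circle centre at depth rc on the axis; at depth x the half-chord is
    half <- sqrt(rc^2 - (rc - x)^2)
    gm <- geometry_model(R = R, H = H, L = max(3, H * 2), D = 25)
    expect_equal(thickness(x, gm), 2 * half, tolerance = 1e-10)
  }
})

test_that("growth curve properties and velocity field match the model", {
  g <- growth_model()           # fitted study values
  expect_equal(growth_percent(g, 0), 5.8697 - 5.6924)  # 0.1773 %
  expect_equal(growth_percent(g, Inf), g$a1)
  expect_equal(velocity_field(0, 100, g), 0)
  expect_equal(velocity_field(1, 0, g), -5.6924 / (100 * 588.23),
               tolerance = 1e-6)                       # -9.677e-5 mm/min
  # uniform dilation rate: v strictly linear in x
  expect_equal(velocity_field(2, 50, g), 2 * velocity_field(1, 50, g))
  expect_equal(velocity_field(0.2, 50, g), 0.2 * velocity_field(1, 50, g))
  expect_error(velocity_field(1, -5, g), "t must be")
  expect_error(growth_model(tau = 0), "tau")
})

test_that("velocity field integrates to the height change", {
  # a particle advected by v(x, t) from x0 should follow
  # X(t) = x0 * (1 + g(0)/100) / (1 + g(t)/100); forward-Euler at fine dt
  g <- growth_model()
  x <- 1; dt <- 0.01; tt <- seq(0, 600, by = dt)
  for (t in tt[-length(tt)]) x <- x + dt * velocity_field(x, t, g)
  # exact characteristic of the stated v: exponential in g/100
  exact <- exp(growth_percent(g, 0) / 100) / exp(growth_percent(g, 600) / 100)
  expect_equal(x, exact, tolerance = 1e-4)
  # and, to second order in the few-percent growth, the height-ratio form
  ratio_form <- (1 + growth_percent(g, 0) / 100) /
    (1 + growth_percent(g, 600) / 100)
  expect_equal(x, ratio_form, tolerance = 2e-3)
})

test_that("growth fit recovers parameters and handles edge cases", {
  g <- growth_model()
  t <- seq(0, 1320, by = 10)
  fit <- fit_growth(t, growth_percent(g, t))
  expect_equal(signif(fit$growth$a1, 4), signif(g$a1, 4))
  expect_equal(signif(fit$growth$a2, 4), signif(g$a2, 4))
  expect_equal(signif(fit$growth$tau, 4), signif(g$tau, 4))
  expect_lt(fit$SE_res, 1e-8)
  expect_equal(fit$df, length(t) - 3)

  flat <- fit_growth(seq(0, 60, 10), rep(0, 7))
  expect_equal(flat$SE_res, 0)
  expect_equal(growth_percent(flat$growth, 30), 0)

  set.seed(3)
  noisy <- fit_growth(t, growth_percent(g, t) + rnorm(length(t), sd = 0.2))
  expect_lt(abs(noisy$growth$a1 - g$a1) / g$a1, 0.10)

  expect_error(fit_growth(c(0, 1, 2), c(0, 1, 2)), "at least 4")
})
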