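#' Tissue projection geometry of a curved-cap cylindrical punch
#'
#' The biopsy punch is modelled as a cylinder of diameter `R` whose upper
#' (cortical) surface is a curved cap of height `H`.  The cap is the section
#' of a circle through the apex and the cap rim, so the projected beam-path
#' length through the sample at depth `x` below the apex is the chord of
#' that circle (see [thickness()]).
#'
#' @param R Punch diameter in mm (the cylinder diameter).
#' @param H Cap height in mm; must satisfy `0 < H < L`.  `H = 0` is accepted
#'   as a degenerate "flat" geometry with `d(x) = R` everywhere, used by
#'   analytic oracles.
#' @param D Vial (staining-solution column) diameter in mm.
#' @param L Maximum modelled depth in mm.
#' @return An object of class `geometry_model`.
#' @seealso [thickness()], [curvature_radius()]
#' @export
geometry_model <- function(R = 4, H = 0.4, D = 25, L = 3) {
  stopifnot(is.numeric(R), is.numeric(H), is.numeric(D), is.numeric(L))
  if (H < 0) stop("cap height H must be >= 0")
  if (H > 0 && !(H < L)) stop("geometry requires 0 < H < L")
  if (!(L <= D)) stop("geometry requires L <= D")
  if (!(R <= D)) stop("geometry requires R <= D")
  structure(list(R = R, H = H, D = D, L = L), class = "geometry_model")
}

#' Projected sample thickness at depth x
#'
#' Chord length of the surface-curvature circle at depth `x` from the apex:
#' `d(x) = 2 * sqrt(x/H * (H^2 + R^2/4) - x^2)` for `0 <= x <= H` and
#' `d(x) = R` for `x > H`.  For the degenerate flat geometry (`H = 0`) the
#' thickness is `R` at every depth.
#'
#' @param x Depth(s) from the sample surface, mm; must be `>= 0`.
#' @param geom A [geometry_model()].
#' @return Thickness in mm, vectorised over `x`.
#' @export
thickness <- function(x, geom) {
  stopifnot(inherits(geom, "geometry_model"))
  if (any(x < 0)) stop("depth x must be >= 0 (x < 0 is outside the sample)")
  if (geom$H <= 0) return(rep(geom$R, length(x)))
  arg <- x / geom$H * (geom$H^2 + geom$R^2 / 4) - x^2
  d <- 2 * sqrt(pmax(arg, 0))
  d[x >= geom$H] <- geom$R
  d
}

#' Radius of the surface-curvature circle
#'
#' The cap surface is approximated by the circle through the apex and the
#' cap rim, with radius `(H^2 + R^2/4) / (2 H)`.  In the hemispherical
#' limit `H = R/2` this reduces to `R/2`.
#'
#' @inheritParams thickness
#' @return Radius in mm.
#' @export
curvature_radius <- function(geom) {
  stopifnot(inherits(geom, "geometry_model"))
  if (geom$H <= 0) stop("degenerate geometry: curvature undefined for H = 0")
  (geom$H^2 + geom$R^2 / 4) / (2 * geom$H)
}

#' Monomolecular tissue-expansion model
#'
#' Percent change in sample height during incubation follows the saturating
#' growth curve `g(t) = a1 - a2 * exp(-t / tau)` with `g(Inf) = a1` and
#' near-zero initial change `g(0) = a1 - a2`.
#'
#' @param a1 Asymptotic height change, percent.
#' @param a2 Amplitude of the saturating term, percent.
#' @param tau Time constant, minutes; must be positive.
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(a1 = 5.8697, a2 = 5.6924, tau = 588.23) {
  stopifnot(is.numeric(a1), is.numeric(a2), is.numeric(tau))
  if (tau <= 0) stop("growth time constant tau must be > 0")
  structure(list(a1 = a1, a2 = a2, tau = tau), class = "growth_model")
}

#' Evaluate the growth curve g(t)
#'
#' @param growth A [growth_model()].
#' @param t Time(s) since staining onset, minutes.
#' @return Percent height change, vectorised over `t`.
#' @export
growth_percent <- function(growth, t) {
  stopifnot(inherits(growth, "growth_model"))
  growth$a1 - growth$a2 * exp(-t / growth$tau)
}

#' Expansion-induced velocity field
#'
#' Under isotropic expansion the growth curve induces the flow
#' `v(x, t) = -x * a2 / (100 * tau) * exp(-t / tau)` (mm/min) used by the
#' advection terms of the staining model.  Note the sign: in the model's
#' surface-referenced coordinates expansion gives `v < 0` for `x > 0`
#' (material drifts towards the surface origin), which is counter-intuitive
#' but is the convention the standardized profiles are expressed in.
#'
#' @param x Depth(s), mm.
#' @param t Time(s), minutes; must be `>= 0`.
#' @param growth A [growth_model()].
#' @return Velocity in mm/min.
#' @export
velocity_field <- function(x, t, growth) {
  stopifnot(inherits(growth, "growth_model"))
  if (any(t < 0)) stop("t must be >= 0")
  -x * growth$a2 / (100 * growth$tau) * exp(-t / growth$tau)
}

#' Fit the monomolecular growth model to a height-change series
#'
#' Least-squares fit of `g(t) = a1 - a2 exp(-t/tau)` to measured percent
#' height changes.  Initialisation: `a1` from the last observation, `a2`
#' from the total rise, `tau` from the time of half-rise; `tau` is bounded
#' in `(0, 10 * max(t)]`.  A flat series at zero is handled on the
#' degenerate branch `a1 = a2` (so `g` is identically its fitted residual
#' level) without invoking the optimizer.
#'
#' @param t Times, minutes (>= 4 points).
#' @param pct Percent height change at `t`.
#' @return A list with the fitted [growth_model()] in `$growth`, the
#'   residual standard error `$SE_res` (df = n - 3), `$df` and `$fitted`.
#' @export
fit_growth <- function(t, pct) {
  stopifnot(length(t) == length(pct))
  if (length(t) < 4) stop("growth fit needs at least 4 time points")
  n <- length(t)
  if (all(abs(pct) < 1e-12)) {
    g <- growth_model(a1 = 0, a2 = 0, tau = max(t) / 2)
    return(list(growth = g, SE_res = 0, df = n - 3, fitted = rep(0, n)))
  }
  a1_0 <- pct[which.max(t)]
  a2_0 <- a1_0 - pct[which.min(t)]
  half <- pct[which.min(t)] + 0.5 * a2_0
  tau_0 <- t[which.min(abs(pct - half))]
  if (!is.finite(tau_0) || tau_0 <= 0) tau_0 <- max(t) / 4
  fit <- minpack.lm::nls.lm(
    par = c(a1 = a1_0, a2 = a2_0, log_tau = log(tau_0)),
    fn = function(p) pct - (p[1] - p[2] * exp(-t / exp(p[3]))),
    lower = c(-Inf, -Inf, log(max(t) * 1e-6)),
    upper = c(Inf, Inf, log(10 * max(t))),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info < 1 || fit$info > 4)
    stop("growth fit did not converge: ", fit$message)
  p <- fit$par
  g <- growth_model(a1 = p[[1]], a2 = p[[2]], tau = exp(p[[3]]))
  fitted <- growth_percent(g, t)
  se <- sqrt(sum((pct - fitted)^2) / (n - 3))
  list(growth = g, SE_res = se, df = n - 3, fitted = fitted)
}
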