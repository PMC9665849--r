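#' Fitting domain for the kinetic inverse problem
#'
#' @param depth Depth interval in mm (default 100-700 um from the surface).
#' @param time Time interval in minutes (default 0-1200 min).
#' @return An object of class `fit_domain`.
#' @export
fit_domain <- function(depth = c(0.100, 0.700), time = c(0, 1200)) {
  stopifnot(length(depth) == 2, length(time) == 2,
            depth[1] < depth[2], time[1] < time[2])
  structure(list(depth = depth, time = time), class = "fit_domain")
}

#' Estimate the solution concentration from a standardized profile
#'
#' Averages the standardized absorbance over the solution window
#' (default -150 to -50 um) and `t` in `[0, 1200]` min, and divides by the
#' vial diameter and the intensity-to-concentration scaling factor.
#'
#' @param profile An [intensity_profile()] at stage `standardized_uhat`.
#' @param D Vial diameter, mm.
#' @param F_I2C Intensity-to-concentration scaling factor.
#' @param window Solution depth window, mm.
#' @param time_interval Time interval averaged over, minutes.
#' @return Estimated concentration `C0` in mmol/mm^3.
#' @export
estimate_C0 <- function(profile, D = 25, F_I2C = 214.6308,
                        window = c(-0.150, -0.050),
                        time_interval = c(0, 1200)) {
  .check_stage(profile, "standardized_uhat")
  rows <- profile$depth >= window[1] & profile$depth <= window[2]
  cols <- profile$time >= time_interval[1] & profile$time <= time_interval[2]
  if (!any(rows) || !any(cols))
    stop("window error: empty solution window on this grid")
  mean(profile$values[rows, cols, drop = FALSE]) / (D * F_I2C)
}

#' Residual standard error
#'
#' `sqrt(sum(residual^2) / df)` between congruent observed and modelled
#' matrices.
#'
#' @param observed,modelled Matrices of identical shape.
#' @param df Degrees of freedom (> 0).
#' @return Scalar residual standard error.
#' @export
residual_standard_error <- function(observed, modelled, df) {
  stopifnot(all(dim(as.matrix(observed)) == dim(as.matrix(modelled))))
  if (df <= 0) stop("degrees-of-freedom error: df must be > 0")
  sqrt(sum((observed - modelled)^2) / df)
}

#' Default box bounds for the six-parameter fit
#'
#' Brackets physically plausible values: `De` in `[1e-5, 1e-1]` mm^2/min,
#' rate constants in `[1e-2, 1e6]`, site densities in `[0, 2e-3]`
#' mmol/mm^3, cap height in `[0.05, 1.5]` mm.
#'
#' @return List with `lower` and `upper` named vectors.
#' @export
kinetic_fit_bounds <- function() {
  list(lower = c(De = 1e-5, kon = 1e-2, kunmask = 1e-2,
                 S0 = 0, M0 = 0, H = 0.05),
       upper = c(De = 1e-1, kon = 1e6, kunmask = 1e6,
                 S0 = 2e-3, M0 = 2e-3, H = 1.5))
}

# internal parameter transform: optimise log10 of De/kon/kunmask,
# site densities in units of 1e-4 mmol/mm^3, H in mm
.to_scaled <- function(p) c(log10(p[["De"]]), log10(p[["kon"]]),
                            log10(p[["kunmask"]]), p[["S0"]] * 1e4,
                            p[["M0"]] * 1e4, p[["H"]])
.from_scaled <- function(q) c(De = 10^q[1], kon = 10^q[2],
                              kunmask = 10^q[3], S0 = q[4] * 1e-4,
                              M0 = q[5] * 1e-4, H = q[6])

#' Fit the six kinetic/geometry parameters to a standardized profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, \pkg{minpack.lm})
#' minimising the squared mismatch between the observed standardized
#' absorbance and the modelled intensity `F_I2C (o + f + b)` over the fit
#' domain.  Each residual evaluation runs [simulate_staining()] with the
#' candidate `De, kon, kunmask, S0, M0` and cap height `H`.  `De`, `kon`
#' and `kunmask` are optimised on a log10 scale; forward runs are memoised
#' on the parameter vector.  Solution concentration `C0` is fixed at the
#' [estimate_C0()] value, not fitted.
#'
#' @param profile An [intensity_profile()] at stage `standardized_uhat`
#'   covering the fit domain (and, for the default `C0`, the solution
#'   window).
#' @param geom A [geometry_model()] providing the fixed `R`, `D`, `L`; its
#'   `H` is replaced by the candidate value during fitting.
#' @param growth A [growth_model()] or `NULL`.
#' @param domain A [fit_domain()].
#' @param init Named vector of starting values
#'   (`De, kon, kunmask, S0, M0, H`); defaults to data-driven heuristics.
#' @param bounds List with `lower`/`upper` named vectors, see
#'   [kinetic_fit_bounds()].
#' @param C0 Solution concentration; default estimated from the profile.
#' @param F_I2C Intensity-to-concentration scaling factor.
#' @param sim_nodes Grid nodes for the embedded forward simulations.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @param rtol,atol Forward-solver tolerances during fitting.  Tighter
#'   than the simulation defaults so that the finite-difference Jacobian
#'   of the objective is not dominated by integrator noise.
#' @param epsfcn Relative squared step for the finite-difference Jacobian
#'   (see [minpack.lm::nls.lm.control()]); sized to clear the forward
#'   solver's error floor.
#' @return A `kinetic_fit` object: list with `params` (fitted
#'   [kinetic_params()]), `H`, `SE_res` (df = n_obs - 6), `n_obs`, `df`,
#'   `converged`, `trace` (objective per accepted evaluation), `modelled`
#'   (fitted intensity on the fit grid), `depth`, `time`.
#' @export
fit_kinetics <- function(profile, geom, growth = NULL,
                         domain = fit_domain(), init = NULL,
                         bounds = kinetic_fit_bounds(),
                         C0 = NULL, F_I2C = 214.6308,
                         sim_nodes = 301L, maxiter = 100L,
                         rtol = 1e-8, atol = 1e-11, epsfcn = 1e-8) {
  .check_stage(profile, "standardized_uhat")
  stopifnot(inherits(geom, "geometry_model"))
  if (min(profile$depth) > domain$depth[1] ||
      max(profile$depth) < domain$depth[2] ||
      min(profile$time) > domain$time[1] ||
      max(profile$time) < domain$time[2])
    stop("profile does not cover the fit domain")
  rows <- profile$depth >= domain$depth[1] & profile$depth <= domain$depth[2]
  cols <- profile$time >= domain$time[1] & profile$time <= domain$time[2]
  if (sum(rows) < 3 || sum(cols) < 3)
    stop("profile does not cover the fit domain")
  obs <- profile$values[rows, cols, drop = FALSE]
  x_fit <- profile$depth[rows]
  t_fit <- profile$time[cols]
  if (is.null(C0)) C0 <- estimate_C0(profile, D = geom$D, F_I2C = F_I2C)

  if (is.null(init)) {
    u_sol <- F_I2C * C0 * geom$D
    plateau <- max(obs) - u_sol
    S0_0 <- min(max(plateau / (F_I2C * geom$R), 1e-5), 1.9e-3)
    # front-speed heuristic for De from the last fitted time column
    thr <- u_sol + 0.5 * plateau
    last <- obs[, ncol(obs)]
    idx <- which(last < thr)
    x_front <- if (length(idx)) x_fit[idx[1]] else max(x_fit)
    De_0 <- min(max(x_front^2 / (4 * max(t_fit)), 2e-5), 5e-2)
    init <- c(De = De_0, kon = 1e2, kunmask = 1e2,
              S0 = S0_0, M0 = S0_0 / 3, H = 0.4)
  }
  init <- init[c("De", "kon", "kunmask", "S0", "M0", "H")]
  if (any(init < bounds$lower | init > bounds$upper))
    stop("init outside bounds")

  tt <- sort(unique(c(0, t_fit)))
  keep <- match(t_fit, tt)
  cache <- new.env(parent = emptyenv())
  trace <- numeric(0)
  forward <- function(q) {
    key <- paste(signif(q, 12), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- .from_scaled(q)
    g <- geometry_model(R = geom$R, H = p[["H"]], D = geom$D, L = geom$L)
    kp <- kinetic_params(De = p[["De"]], kon = p[["kon"]],
                         kunmask = p[["kunmask"]], S0 = p[["S0"]],
                         M0 = p[["M0"]], C0 = C0, F_I2C = F_I2C)
    mod <- tryCatch({
      traj <- simulate_staining(kp, g, growth, times = tt,
                                n_nodes = sim_nodes,
                                rtol = rtol, atol = atol)
      ih <- project_intensity(traj)
      t(vapply(seq_along(keep), function(j)
        stats::approx(traj$x, ih[, keep[j]], xout = x_fit)$y,
        numeric(length(x_fit))))
    }, error = function(e) {
      warning("forward simulation failed (", conditionMessage(e),
              "); penalised")
      NULL
    })
    val <- if (is.null(mod)) matrix(1e3, length(t_fit), length(x_fit))
           else mod
    cache[[key]] <- val
    val
  }
  resid_fn <- function(q) {
    mod <- forward(q)
    r <- as.vector(obs - t(mod))
    trace <<- c(trace, sum(r^2))
    r
  }
  fit <- minpack.lm::nls.lm(
    par = .to_scaled(init), fn = resid_fn,
    lower = .to_scaled(pmax(bounds$lower,
                            c(1e-12, 1e-12, 1e-12, 0, 0, 0))),
    upper = .to_scaled(bounds$upper),
    control = minpack.lm::nls.lm.control(maxiter = maxiter, nprint = 0,
                                         epsfcn = epsfcn))
  p <- .from_scaled(fit$par)
  mod <- t(forward(fit$par))
  n_obs <- length(obs)
  df <- n_obs - 6
  se <- residual_standard_error(obs, mod, df)
  structure(list(
    params = kinetic_params(De = p[["De"]], kon = p[["kon"]],
                            kunmask = p[["kunmask"]], S0 = p[["S0"]],
                            M0 = p[["M0"]], C0 = C0, F_I2C = F_I2C),
    H = p[["H"]], SE_res = se, n_obs = n_obs, df = df,
    converged = fit$info %in% 1:4, info = fit$info,
    message = fit$message, trace = trace,
    modelled = mod, depth = x_fit, time = t_fit),
    class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  p <- x$params
  cat("<kinetic_fit> ", if (x$converged) "converged" else "NOT converged",
      " (", x$n_obs, " obs, df = ", x$df, ")\n", sep = "")
  cat(sprintf("  De      = %.4g mm^2/min\n", p$De))
  cat(sprintf("  kon     = %.4g (mmol/mm^3)^-1 min^-1\n", p$kon))
  cat(sprintf("  kunmask = %.4g (mmol/mm^3)^-1 min^-1\n", p$kunmask))
  cat(sprintf("  S0      = %.4g mmol/mm^3\n", p$S0))
  cat(sprintf("  M0      = %.4g mmol/mm^3\n", p$M0))
  cat(sprintf("  H       = %.4g mm\n", x$H))
  cat(sprintf("  C0      = %.4g mmol/mm^3 (fixed)\n", p$C0))
  cat(sprintf("  SE_res  = %.4g\n", x$SE_res))
  invisible(x)
}
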