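#' Kinetic parameters of the staining model
#'
#' The six fitted quantities of the diffusion-reaction-advection model plus
#' the fixed constants.  Units: `De` mm^2/min; `kon` and `kunmask`
#' (mmol/mm^3)^-1 min^-1 (rates acting on volumetric concentrations);
#' `S0`, `M0`, `C0`, `B0` mmol/mm^3; `F_I2C` standardized-intensity units
#' per (mmol/mm^3 * mm) of projected density.
#'
#' @param De Effective diffusion coefficient of free OsO4.
#' @param kon Binding rate constant (free osmium + available site -> bound).
#' @param kunmask Unmasking rate constant (masked site + free osmium ->
#'   available site).
#' @param S0 Initial volumetric density of available binding sites.
#' @param M0 Initial volumetric density of masked binding sites.
#' @param C0 Free OsO4 concentration of the staining solution.  The default
#'   is the concentration at which the intensity standardization is exactly
#'   anchored (about 82.7 nmol/mm^3, the measured level of a 2% solution).
#' @param B0 Bound-density boundary coefficient at `x = L`; 0 is the only
#'   value consistent with the initial condition `b(x, 0) = 0`.
#' @param F_I2C Intensity-to-concentration scaling factor.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(De = 7e-4, kon = 5e3, kunmask = 20,
                           S0 = 3.54e-4, M0 = 1.2e-4,
                           C0 = solution_C0(), B0 = 0,
                           F_I2C = 214.6308) {
  vals <- c(De = De, kon = kon, kunmask = kunmask, S0 = S0, M0 = M0, C0 = C0)
  if (any(vals < 0))
    stop("kinetic parameters must be non-negative: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  structure(list(De = De, kon = kon, kunmask = kunmask, S0 = S0, M0 = M0,
                 C0 = C0, B0 = B0, F_I2C = F_I2C),
            class = "kinetic_params")
}

#' Solution concentration anchored to the intensity standardization
#'
#' The standardization map is constructed so that the staining solution sits
#' at the standardized level `u_sol = (10 (1 + a) - 9) / (10 (1 + a))`
#' (0.443584 for the default `a = 0.61749`).  Dividing by the vial diameter
#' and the intensity-to-concentration factor gives the corresponding free
#' OsO4 concentration, about 82.7 nmol/mm^3 for a 2% solution.
#'
#' @param a Standardization factor.
#' @param D Vial diameter, mm.
#' @param F_I2C Intensity-to-concentration scaling factor.
#' @return Concentration in mmol/mm^3.
#' @export
solution_C0 <- function(a = 0.61749, D = 25, F_I2C = 214.6308) {
  u_sol <- (10 * (1 + a) - 9) / (10 * (1 + a))
  u_sol / (D * F_I2C)
}

#' Initial state of the staining model
#'
#' Populates the state exactly as specified by the model's initial
#' conditions: no free or bound osmium inside the tissue
#' (`f(x > 0) = 0`, `b = 0`), available and masked sites proportional to
#' the local projected thickness (`s = S0 d(x)`, `m = M0 d(x)`), and
#' solution osmium filling the rest of the beam path
#' (`o = C0 (D - d(x))`).  The surface node `x = 0` carries the boundary
#' values `f = C0 R`, `b = s = m = 0`, `o = C0 (D - R)`, held as a
#' Dirichlet condition during integration.
#'
#' @param params A [kinetic_params()].
#' @param geom A [geometry_model()].
#' @param x Depth grid (uniform, starting at 0), mm.
#' @return A matrix with columns `f, b, s, m, o` (projected densities,
#'   mmol/mm^2) and one row per grid node.
#' @export
initial_state <- function(params, geom, x) {
  stopifnot(inherits(params, "kinetic_params"), inherits(geom, "geometry_model"))
  if (geom$H > geom$L) stop("geometry error: cap height H exceeds domain L")
  d <- thickness(x, geom)
  st <- cbind(f = rep(0, length(x)),
              b = rep(0, length(x)),
              s = params$S0 * d,
              m = params$M0 * d,
              o = params$C0 * (geom$D - d))
  st[1, ] <- c(params$C0 * geom$R, 0, 0, 0, params$C0 * (geom$D - geom$R))
  st
}

#' Simulate the coupled staining model
#'
#' Method-of-lines solution of the coupled system for the projected
#' densities of free osmium `f`, bound osmium `b`, available sites `s`,
#' masked sites `m` and solution osmium outside the sample `o`:
#' \deqn{f_t = D_e f_{xx} - k_{on} s f / d - (f v)_x}
#' \deqn{b_t = k_{on} s f / d - (b v)_x}
#' \deqn{s_t = -k_{on} s f / d + k_{un} m f / d - (s v)_x}
#' \deqn{m_t = -k_{un} m f / d - (m v)_x}
#' \deqn{o_t = -(o v)_x}
#' with a Dirichlet condition at the surface (`f(0,t) = C0 R`) and zero
#' flux at `x = L`.  Reactions couple volumetric concentrations, i.e. the
#' projected densities divided by the local path length `d(x)` floored at
#' `d(dx/2)`, which keeps the rate constants geometry-independent; set
#' `reaction_on_projected = TRUE` for the literal projected-density
#' products.  Advection uses conservative first-order upwinding of the
#' flux `(c v)` with `v` from [velocity_field()]; `growth = NULL` turns
#' advection off.  Integration uses the stiff `lsoda` solver of
#' \pkg{deSolve} with a banded Jacobian.
#'
#' @param params A [kinetic_params()].
#' @param geom A [geometry_model()].
#' @param growth A [growth_model()] or `NULL` for a static domain.
#' @param times Output times, minutes; increasing, starting at 0.
#' @param n_nodes Number of grid nodes on `[0, L]` (default 301).
#' @param closed If `TRUE`, integrate the closed-system variant: zero flux
#'   at both ends, no Dirichlet source; supply the initial free-osmium
#'   profile via `f0`.  Used for mass-balance verification.
#' @param f0 Optional initial free-osmium projected density (closed system).
#' @param reaction_on_projected Evaluate reaction products on projected
#'   densities literally instead of volumetric concentrations.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `staining_trajectory`: list with `x`, `times`,
#'   and depth-by-time matrices `f`, `b`, `s`, `m`, `o`.
#' @export
simulate_staining <- function(params, geom, growth = NULL, times,
                              n_nodes = 301L, closed = FALSE, f0 = NULL,
                              reaction_on_projected = FALSE,
                              rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(params, "kinetic_params"), inherits(geom, "geometry_model"))
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0")
  n <- as.integer(n_nodes)
  x <- seq(0, geom$L, length.out = n)
  dx <- x[2] - x[1]
  if (length(times) > 1) {
    dt_rep <- min(diff(times))
    if (params$De > 0 && dx > sqrt(params$De * dt_rep) / 4 && dt_rep < 1e6)
      warning("grid spacing may under-resolve the diffusion boundary layer")
  }
  st <- initial_state(params, geom, x)
  if (closed) {
    st[1, ] <- c(0, 0, params$S0 * thickness(x[1], geom),
                 params$M0 * thickness(x[1], geom),
                 params$C0 * (geom$D - thickness(x[1], geom)))
    if (!is.null(f0)) {
      stopifnot(length(f0) == n)
      st[, "f"] <- f0
    }
  }
  y0 <- as.vector(t(st))  # interleaved (f,b,s,m,o) per node
  has_growth <- !is.null(growth)
  if (has_growth) stopifnot(inherits(growth, "growth_model"))
  dmin <- if (geom$H > 0) thickness(dx / 2, geom) else geom$R
  p <- c(params$De, params$kon, params$kunmask,
         if (has_growth) growth$a2 / (100 * growth$tau) else 0,
         if (has_growth) 1 / growth$tau else 0,
         as.numeric(has_growth), as.numeric(closed), dx,
         geom$R, geom$H, dmin, as.numeric(reaction_on_projected))
  out <- deSolve::ode(y = y0, times = times, func = "stain_derivs",
                      parms = p, dllname = "stainkinetics",
                      initfunc = "stain_initmod",
                      method = "lsoda", jactype = "bandint",
                      bandup = 5L, banddown = 5L,
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed at t = ", max(out[, 1]),
         "; consider a finer grid or looser tolerances")
  sol <- out[, -1, drop = FALSE]
  floor_lim <- -10 * atol
  if (min(sol) < -10 * max(atol, 1e-12) * 1e3 && min(sol) < -1e-6)
    stop("stability error: strongly negative state encountered; ",
         "use a finer grid")
  species <- c("f", "b", "s", "m", "o")
  traj <- list(x = x, times = times)
  for (k in seq_along(species)) {
    m <- t(sol[, seq(k, ncol(sol), by = 5), drop = FALSE])  # depth x time
    m[m < 0 & m > floor_lim] <- 0
    dimnames(m) <- NULL
    traj[[species[k]]] <- m
  }
  traj$params <- params
  traj$geom <- geom
  traj$growth <- if (has_growth) growth else NULL
  traj$closed <- closed
  class(traj) <- "staining_trajectory"
  traj
}

#' Modelled projection intensity
#'
#' The modelled counterpart of the standardized absorbance profile:
#' `I(x, t) = F_I2C * (o + f + b)`, elementwise over the trajectory grid.
#'
#' @param traj A [simulate_staining()] trajectory.
#' @param params A [kinetic_params()]; defaults to the trajectory's own.
#' @return Depth-by-time matrix on the trajectory grids.
#' @export
project_intensity <- function(traj, params = traj$params) {
  stopifnot(inherits(traj, "staining_trajectory"))
  params$F_I2C * (traj$o + traj$f + traj$b)
}

#' Mass-balance report for a staining trajectory
#'
#' Bookkeeping harness for the conservation structure of the model:
#' reports the relative drift of the total osmium content
#' `integral of (f + b) dx` (meaningful for closed-system runs, where it
#' must be conserved), and the maximum pointwise drift of `s + m + b`,
#' which is exactly invariant when the velocity field is off.
#'
#' @param traj A [simulate_staining()] trajectory on a uniform grid.
#' @return A list with `total_fb` (per-time totals), `rel_drift_fb`,
#'   `max_rel_drift_smb`.
#' @export
mass_balance <- function(traj) {
  stopifnot(inherits(traj, "staining_trajectory"))
  dx <- traj$x[2] - traj$x[1]
  w <- rep(dx, length(traj$x)); w[1] <- w[length(w)] <- dx / 2  # trapezoid
  total_fb <- as.vector(w %*% (traj$f + traj$b))
  rel_fb <- if (total_fb[1] > 0)
    max(abs(total_fb - total_fb[1])) / total_fb[1] else NA_real_
  smb <- traj$s + traj$m + traj$b
  ref <- smb[, 1]
  scale <- pmax(abs(ref), max(abs(ref)) * 1e-3)
  rel_smb <- max(abs(smb - ref) / scale)
  list(total_fb = total_fb, rel_drift_fb = rel_fb,
       max_rel_drift_smb = rel_smb)
}

#' @export
print.staining_trajectory <- function(x, ...) {
  cat("<staining_trajectory> ", length(x$x), " depth nodes on [0, ",
      max(x$x), "] mm, ", length(x$times), " times on [",
      min(x$times), ", ", max(x$times), "] min\n", sep = "")
  cat("  species: f, b, s, m, o (projected densities, mmol/mm^2)\n")
  invisible(x)
}

#' @export
plot.staining_trajectory <- function(x, species = "b", ...) {
  m <- x[[species]]
  graphics::image(x$x, x$times, m, xlab = "depth (mm)", ylab = "time (min)",
                  main = paste("projected", species),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
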