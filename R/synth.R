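#' Molar concentration of an OsO4 solution
#'
#' Converts percent weight/volume to volumetric molar concentration using
#' the molar mass of OsO4 (254.23 g/mol): 1% w/v = 39.34 nmol/mm^3.
#'
#' @param pct Concentration in % w/v (g per 100 mL).
#' @return Concentration in mmol/mm^3.
#' @export
oso4_concentration <- function(pct) {
  if (any(pct < 0)) stop("domain error: concentration must be >= 0")
  pct * 10 / 254.23 * 1e-3
}

#' Detector calibration of the synthetic intensity chain
#'
#' Solves for the detector gain/offset pair that makes the
#' baseline-correction + standardization chain the exact inverse of the
#' synthetic image formation `u = gain * uhat + offset`,
#' `w = full_scale - u`.  The standardization anchors admit such an exact
#' inverse only when the solution sits at the standardized level
#' `u_sol = (10(1+a) - 9)/(10(1+a))`; given that, the offset follows from
#' the gain in closed form: `offset = gain * (9/(10(1+a)) - u_sol) - m`.
#'
#' @param gain Intensity units per unit standardized intensity.
#' @param params A [standardization_params()].
#' @return List with `gain`, `offset`, and the anchored solution level
#'   `u_sol`.
#' @export
detector_calibration <- function(gain = 14500,
                                 params = standardization_params()) {
  A <- 1 + params$a
  u_sol <- (10 * A - 9) / (10 * A)
  offset <- gain * (9 / (10 * A) - u_sol) - params$m
  list(gain = gain, offset = offset, u_sol = u_sol)
}

#' Ground truth for synthetic recordings
#'
#' Bundles everything the generators need and everything downstream tests
#' compare against: the kinetic parameters, geometry, growth curve,
#' per-frame translations, noise scale, cone-beam bias coefficients and
#' the random seed.
#'
#' @param kinetics A [kinetic_params()].
#' @param geometry A [geometry_model()].
#' @param growth A [growth_model()] or `NULL` (static sample).
#' @param shifts n-by-2 matrix of true per-frame translations in pixels
#'   (row, col), or `NULL` to draw whole-pixel jitter uniformly from
#'   -5..5 px per axis (frame 1 fixed at zero) when a stack is generated.
#' @param noise_sigma Additive Gaussian noise scale: detector a.u. for
#'   stacks, standardized-intensity units for profile matrices.
#' @param bias_coeffs Five coefficients `c(b1, b2, b3, b4, b5)` of the
#'   quadratic log-intensity bias `Z = b5 x^2 + b4 y^2 + b3 x + b2 y + b1`
#'   on coordinates normalised to \[-1, 1\]; the field is normalised to a
#'   peak of one before use, so only its shape matters.
#' @param sample_height Punch height above the vial bottom, mm.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param sim_nodes Grid nodes used by the embedded forward simulation.
#' @return An object of class `synth_ground_truth`.
#' @export
synth_ground_truth <- function(kinetics = kinetic_params(),
                               geometry = geometry_model(),
                               growth = growth_model(),
                               shifts = NULL,
                               noise_sigma = 0,
                               bias_coeffs = c(0, 0.02, -0.03, -0.12, -0.08),
                               sample_height = 1,
                               seed = 1L,
                               sim_nodes = 301L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(kinetics = kinetics, geometry = geometry, growth = growth,
                 shifts = shifts, noise_sigma = noise_sigma,
                 bias_coeffs = bias_coeffs, sample_height = sample_height,
                 seed = as.integer(seed), sim_nodes = as.integer(sim_nodes)),
            class = "synth_ground_truth")
}

#' Acquisition settings for synthetic stacks
#'
#' @param frame_interval Minutes between frames (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param pixel_size mm per pixel.
#' @param image_shape `c(rows, cols)`.
#' @param detector_full_scale Detector full scale, a.u.
#' @param t_start Acquisition onset, minutes after staining onset.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_interval = 20, n_frames = 40,
                             pixel_size = 0.02, image_shape = c(160, 260),
                             detector_full_scale = 10000, t_start = 6) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 detector_full_scale = detector_full_scale,
                 t_start = t_start),
            class = "acquisition_spec")
}

# forward-model standardized intensity on arbitrary grids;
# negative depths take the constant solution level F_I2C * C0 * D
.model_uhat <- function(truth, depth_grid, time_grid) {
  kp <- truth$kinetics
  tt <- sort(unique(c(0, time_grid)))
  traj <- simulate_staining(kp, truth$geometry, truth$growth, times = tt,
                            n_nodes = truth$sim_nodes)
  uhat_sim <- project_intensity(traj)
  keep <- match(time_grid, tt)
  u_sol <- kp$F_I2C * kp$C0 * truth$geometry$D
  vals <- matrix(u_sol, length(depth_grid), length(time_grid))
  pos <- depth_grid >= 0
  if (any(pos)) {
    xq <- pmin(depth_grid[pos], max(traj$x))
    for (j in seq_along(keep)) {
      vals[pos, j] <- stats::approx(traj$x, uhat_sim[, keep[j]], xout = xq)$y
    }
  }
  vals
}

#' Generate a synthetic standardized profile matrix
#'
#' Evaluates the forward model `uhat(x, t) = F_I2C (o + f + b)` on the
#' requested grids (solution rows at negative depths take the constant
#' solution level) and adds i.i.d. Gaussian noise.  With zero noise the
#' output equals the forward model exactly.
#'
#' @param truth A [synth_ground_truth()].
#' @param depth_grid Strictly increasing depths, mm (may include negative
#'   solution depths).
#' @param time_grid Strictly increasing times, minutes, starting at >= 0.
#' @param noise_sigma Noise scale in standardized-intensity units;
#'   defaults to the truth's.
#' @param seed Seed; defaults to the truth's.
#' @return An [intensity_profile()] at stage `standardized_uhat` with the
#'   ground truth attached as attribute `"ground_truth"`.
#' @export
generate_profile_data <- function(truth, depth_grid, time_grid,
                                  noise_sigma = truth$noise_sigma,
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "synth_ground_truth"))
  if (is.unsorted(depth_grid, strictly = TRUE) ||
      is.unsorted(time_grid, strictly = TRUE))
    stop("invalid-grid error: grids must be strictly increasing")
  vals <- .model_uhat(truth, depth_grid, time_grid)
  if (noise_sigma > 0) {
    set.seed(seed)
    vals <- vals + stats::rnorm(length(vals), sd = noise_sigma)
  }
  out <- intensity_profile(depth_grid, time_grid, vals,
                           stage = "standardized_uhat")
  attr(out, "ground_truth") <- truth
  out
}

# quadratic bias field on [-1, 1]-normalised pixel coordinates,
# normalised to max 0 in the log domain (peak transmission factor 1)
.bias_field <- function(coeffs, shape) {
  yn <- seq(-1, 1, length.out = shape[1])
  xn <- seq(-1, 1, length.out = shape[2])
  Z <- outer(yn, xn, function(y, x)
    coeffs[5] * x^2 + coeffs[4] * y^2 + coeffs[3] * x + coeffs[2] * y +
      coeffs[1])
  Z - max(Z)
}

#' Generate a synthetic projection stack
#'
#' Renders the forward model into detector frames: the punch (diameter `R`,
#' curved cap) sits on the vial bottom; each in-punch column shows the
#' simulated standardized profile anchored at its local surface row (the
#' cap sags towards the punch edges following the curvature circle), the
#' surrounding solution shows the constant solution level, and rows below
#' the vial bottom are rendered as a dense reference band.  Standardized
#' intensity maps to detector units via [detector_calibration()], frames
#' are multiplied by the cone-beam bias `exp(Z)`, translated by the true
#' shifts, and Gaussian noise is added.  The surface row follows
#' `sample_height * (1 + g(t)/100)` rounded to pixels.
#'
#' @param truth A [synth_ground_truth()].
#' @param acq An [acquisition_spec()].
#' @param gain Detector gain passed to [detector_calibration()].
#' @return A list with the [projection_stack()] in `$stack`, the (possibly
#'   completed) `$truth`, the noiseless bias-free rendered line profile
#'   `$line_uhat` (rows-by-frames, averaged over the extraction band), and
#'   the render bookkeeping `$render` (surface rows, bottom row, centre
#'   column, calibration, band half-width).
#' @export
generate_projection_stack <- function(truth, acq, gain = 14500) {
  stopifnot(inherits(truth, "synth_ground_truth"),
            inherits(acq, "acquisition_spec"))
  px <- acq$pixel_size
  nr <- acq$image_shape[1]; nc <- acq$image_shape[2]
  geom <- truth$geometry
  cal <- detector_calibration(gain)
  times <- acq$t_start + (seq_len(acq$n_frames) - 1) * acq$frame_interval

  set.seed(truth$seed)
  shifts <- truth$shifts
  if (is.null(shifts)) {
    # whole-pixel stage repositioning jitter; subpixel drift is exercised
    # separately through explicit fractional `shifts`
    shifts <- cbind(sample(-5:5, acq$n_frames, replace = TRUE),
                    sample(-5:5, acq$n_frames, replace = TRUE))
    shifts[1, ] <- 0
  }
  stopifnot(nrow(shifts) == acq$n_frames)

  half_w_px <- round(geom$R / 2 / px)
  center <- round(nc / 2)
  c_lo <- center - half_w_px; c_hi <- center + half_w_px
  bottom_row <- nr - 12L  # keep the vial-bottom edge in frame under shifts
  g_t <- if (is.null(truth$growth)) rep(0, length(times))
         else growth_percent(truth$growth, times)
  surf_rows <- bottom_row -
    round(truth$sample_height * (1 + g_t / 100) / px)
  if (c_lo < 1 || c_hi > nc || min(surf_rows) < round(0.2 / px) + 1)
    stop("geometry-overflow error: punch footprint (plus 200 um of ",
         "solution above the surface) does not fit the image")

  # simulated standardized profile at one-pixel pitch
  x_model <- seq(0, geom$L, by = px)
  uhat_model <- .model_uhat(truth, x_model, times)
  u_sol <- cal$u_sol
  # cap sag per in-punch column, in integer pixels
  wc <- (seq(c_lo, c_hi) - center) * px
  Rc <- curvature_radius(geom)
  sag_px <- round((Rc - sqrt(pmax(Rc^2 - wc^2, 0))) / px)

  # Rendering is in fixed (vial-anchored) coordinates: depth x measured
  # from the zero-expansion surface position.  Deep tissue (x beyond the
  # cap height) is anchored to the vial bottom and stays put — the model
  # fields already carry the expansion through their advection terms —
  # while the superficial cap segment [x_surf, blend] shows the model's
  # [0, blend] ramp stretched to the current surface position
  # x_surf(t) = -sample_height * g(t)/100, so the visible stained surface
  # rides with the growth curve.
  blend <- max(geom$H, 0.1)
  r0_base <- bottom_row - round(truth$sample_height / px)
  x_surf_mm <- -truth$sample_height * g_t / 100
  model_at <- function(xq, j) {
    idx <- pmin(pmax(round(xq / px), 0L) + 1L, length(x_model))
    uhat_model[idx, j]
  }
  # The vial bottom / Sylgard layer is a dense static band with spatial
  # texture (bubbles, glue, glass structure in real recordings); the
  # texture is what makes frame alignment well-posed in both axes.
  set.seed(truth$seed + 1L)
  band_tex <- matrix(0.92 + stats::runif((nr - bottom_row + 1L) * nc,
                                         -0.07, 0.07),
                     nr - bottom_row + 1L, nc)
  scene_uhat <- function(j) {
    sc <- matrix(u_sol, nr, nc)
    xs <- x_surf_mm[j]
    for (k in seq_along(wc)) {
      col <- c_lo + k - 1
      anchor <- r0_base + sag_px[k]
      rows <- seq(max(anchor - 16L, 1L), bottom_row - 1L)
      x_fix <- (rows - anchor) * px
      vals <- rep(u_sol, length(rows))
      deep <- x_fix >= blend
      capr <- x_fix > xs & !deep
      vals[deep] <- model_at(x_fix[deep], j)
      vals[capr] <- model_at((x_fix[capr] - xs) * blend / (blend - xs), j)
      sc[rows, col] <- vals
    }
    sc[bottom_row:nr, ] <- band_tex
    sc
  }

  bias <- exp(.bias_field(truth$bias_coeffs, c(nr, nc)))
  band <- seq(center - 25L, center + 25L)
  line_uhat <- matrix(NA_real_, nr, acq$n_frames)
  frames <- vector("list", acq$n_frames)
  for (j in seq_len(acq$n_frames)) {
    sc <- scene_uhat(j)
    line_uhat[, j] <- rowMeans(sc[, band])
    w <- acq$detector_full_scale - (cal$gain * sc + cal$offset)
    w <- .translate(w, -shifts[j, 1], -shifts[j, 2]) * bias
    if (truth$noise_sigma > 0)
      w <- w + stats::rnorm(length(w), sd = truth$noise_sigma)
    frames[[j]] <- w
  }
  truth$shifts <- shifts
  list(stack = projection_stack(frames, times, px),
       truth = truth,
       line_uhat = line_uhat,
       render = list(surface_rows = surf_rows, bottom_row = bottom_row,
                     center_col = center, calibration = cal,
                     band_half_width = 25L, times = times))
}

#' Generate solution-only stacks for a concentration series
#'
#' Emulates the calibration measurement relating X-ray absorbance to OsO4
#' concentration: each stack images pure staining solution, so its mean
#' absorbance is `gain * F_I2C * c * D + const` for molar concentration
#' `c`, plus noise — linear in concentration through the shared intensity
#' calibration.
#'
#' @param concentrations Concentrations in % w/v (>= 0).
#' @param acq An [acquisition_spec()]; small frames suffice.
#' @param noise_sigma Additive detector noise, a.u.
#' @param seed Integer seed.
#' @param F_I2C,D Intensity-to-concentration factor and vial diameter.
#' @param gain Detector gain.
#' @return A list of [projection_stack()]s, one per concentration, each
#'   with the concentration attached as attribute `"concentration_pct"`.
#' @export
generate_concentration_series <- function(concentrations,
                                          acq = acquisition_spec(
                                            n_frames = 5,
                                            image_shape = c(40, 40)),
                                          noise_sigma = 0, seed = 1L,
                                          F_I2C = 214.6308, D = 25,
                                          gain = 14500) {
  molar <- oso4_concentration(concentrations)  # validates >= 0
  cal <- detector_calibration(gain)
  set.seed(seed)
  times <- acq$t_start + (seq_len(acq$n_frames) - 1) * acq$frame_interval
  lapply(seq_along(concentrations), function(i) {
    uhat <- F_I2C * molar[i] * D
    frames <- lapply(seq_len(acq$n_frames), function(j) {
      w <- matrix(acq$detector_full_scale - (cal$gain * uhat + cal$offset),
                  acq$image_shape[1], acq$image_shape[2])
      if (noise_sigma > 0)
        w <- w + stats::rnorm(length(w), sd = noise_sigma)
      w
    })
    st <- projection_stack(frames, times, acq$pixel_size)
    attr(st, "concentration_pct") <- concentrations[i]
    st
  })
}
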