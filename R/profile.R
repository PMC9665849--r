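#' Time-ordered projection image stack
#'
#' @param frames List of 2-D intensity matrices (detector scale, a.u.),
#'   all of identical shape.
#' @param timestamps Acquisition times in minutes since staining onset;
#'   strictly increasing, one per frame.
#' @param pixel_size Pixel size in mm.
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(frames, timestamps, pixel_size) {
  stopifnot(is.list(frames), length(frames) == length(timestamps),
            pixel_size > 0)
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 pixel_size = pixel_size),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("<projection_stack> ", length(x$frames), " frames of ", d[1], "x",
      d[2], " px (", x$pixel_size, " mm/px), t in [",
      round(min(x$timestamps), 2), ", ", round(max(x$timestamps), 2),
      "] min\n", sep = "")
  invisible(x)
}

#' Cortical cross-section specification
#'
#' @param origin Pixel coordinate `c(row, col)` of the cortical surface
#'   point where the cross-section starts (depth 0).
#' @param direction Unit 2-vector `c(drow, dcol)` pointing radially into
#'   the tissue.
#' @param half_width Pixels averaged perpendicular to the axis (>= 1).
#' @param depth_extent Depth reach into the tissue, mm.
#' @param solution_extent Reach into the solution above the surface
#'   (negative depths), mm.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(origin, direction = c(1, 0), half_width = 25,
                          depth_extent = 1.5, solution_extent = 0.3) {
  if (half_width < 1) stop("half_width must be >= 1")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-8) stop("direction must have unit norm")
  structure(list(origin = origin, direction = direction,
                 half_width = as.integer(half_width),
                 depth_extent = depth_extent,
                 solution_extent = solution_extent),
            class = "cross_section")
}

#' Standardized-absorbance conversion parameters
#'
#' Constants of the baseline-correction and standardization steps.  The
#' empirical factors `a` and `m` anchor the affine map so that the
#' absorbance-concentration relation passes through the origin and a
#' standardized intensity of about 0.9 corresponds to saturated staining
#' in a 2% OsO4 solution.
#'
#' @param a Dimensionless standardization factor.
#' @param m Standardization intensity anchor, a.u.
#' @param baseline_window Depth interval (mm, both negative) in the
#'   solution used for the per-time baseline.
#' @param b_window Depth interval (mm) used for the across-time mean
#'   baseline-corrected level entering the affine map.
#' @param detector_full_scale Detector intensity full scale, a.u.
#' @return An object of class `standardization_params`.
#' @export
standardization_params <- function(a = 0.61749, m = 6420,
                                   baseline_window = c(-0.150, -0.050),
                                   b_window = c(-0.200, 0),
                                   detector_full_scale = 10000) {
  if (any(baseline_window >= 0)) stop("baseline window must lie at x < 0")
  if (a <= 0) stop("a must be > 0")
  if (m <= 0 || m >= detector_full_scale)
    stop("m must satisfy 0 < m < detector_full_scale")
  structure(list(a = a, m = m, baseline_window = sort(baseline_window),
                 b_window = sort(b_window),
                 detector_full_scale = detector_full_scale),
            class = "standardization_params")
}

#' Spatio-temporal intensity profile
#'
#' Matrix of intensity/absorbance over depth (rows) by time (columns)
#' along a cortical cross-section, together with its processing stage:
#' `raw_w` (transmitted intensity), `absorbance_u`,
#' `baseline_corrected_ub`, or `standardized_uhat`.
#'
#' @param depth Depth grid, mm; 0 at the cortical surface, negative in
#'   solution; strictly increasing.
#' @param time Time grid, minutes; strictly increasing.
#' @param values Depth-by-time matrix of finite values.
#' @param stage Processing stage string.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(depth, time, values,
                              stage = c("raw_w", "absorbance_u",
                                        "baseline_corrected_ub",
                                        "standardized_uhat")) {
  stage <- match.arg(stage)
  if (is.unsorted(depth, strictly = TRUE) ||
      is.unsorted(time, strictly = TRUE))
    stop("invalid grid: depth and time grids must be strictly increasing")
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(depth), ncol(values) == length(time))
  if (!all(is.finite(values))) stop("profile values must be finite")
  structure(list(depth = as.numeric(depth), time = as.numeric(time),
                 values = values, stage = stage),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("<intensity_profile> stage '", x$stage, "': ", length(x$depth),
      " depths [", round(min(x$depth), 3), ", ", round(max(x$depth), 3),
      "] mm x ", length(x$time), " times [", round(min(x$time), 1), ", ",
      round(max(x$time), 1), "] min\n", sep = "")
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  graphics::image(x$depth, x$time, x$values, xlab = "depth (mm)",
                  ylab = "time (min)", main = x$stage,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

.check_stage <- function(profile, expected) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (profile$stage != expected)
    stop("stage error: expected a '", expected, "' profile, got '",
         profile$stage, "'")
}

# bilinear sample of img at fractional (row, col), replicate edges
.bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# shift image content by (-dr, -dc): out(r, c) = img(r + dr, c + dc)
.translate <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  matrix(.bilinear(img, g$r + dr, g$c + dc), nr, nc)
}

# separable box blur with replicated edges (running mean via cumsum)
.boxblur <- function(img, k = 7L) {
  run1 <- function(v) {
    h <- k %/% 2
    vp <- c(rep(v[1], h), v, rep(v[length(v)], h))
    cs <- cumsum(vp)
    (cs[seq_along(v) + 2 * h] - c(0, cs[seq_len(length(v) - 1)])) / k
  }
  t(apply(apply(img, 2, run1), 1, run1))
}

# cross-correlation peak of frame against ref; returns shift (dr, dc) such
# that frame(r, c) ~ ref(r - dr, c - dc), with parabolic subpixel
# refinement.  Both images are high-pass filtered first so that neither
# the smooth illumination bias nor slow staining changes anchor or drag
# the correlation peak; the sharp static structures (vial bottom, punch
# silhouette) then dominate the amplitude-weighted correlation.
.cc_shift <- function(ref, frame) {
  if (sd(ref) == 0 || sd(frame) == 0)
    stop("registration-undefined: frame has no texture")
  a <- ref - .boxblur(ref)
  b <- frame - .boxblur(frame)
  xps <- stats::fft(b) * Conj(stats::fft(a))
  cc <- Re(stats::fft(xps, inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sr0 <- pk[1] - 1; sc0 <- pk[2] - 1
  if (sr0 > nr / 2) sr0 <- sr0 - nr
  if (sc0 > nc / 2) sc0 <- sc0 - nc
  # subpixel refinement: evaluate the correlation on a fine grid around
  # the integer peak by direct (matrix-multiply) DFT upsampling
  fr <- 0:(nr - 1); fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- 0:(nc - 1); fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  fine <- seq(-1, 1, by = 0.05)
  Er <- exp(2i * pi * outer(sr0 + fine, fr) / nr)
  Ec <- exp(2i * pi * outer(fc, sc0 + fine) / nc)
  C <- Re(Er %*% xps %*% Ec)
  pk2 <- which(C == max(C), arr.ind = TRUE)[1, ]
  c(sr0 + fine[pk2[1]], sc0 + fine[pk2[2]])
}

#' Register a projection stack by cross-correlation
#'
#' Aligns every frame to a reference frame by maximising the 2-D
#' cross-correlation (computed via FFT), with parabolic interpolation of
#' the correlation peak for subpixel refinement, then resamples each frame
#' onto the reference grid (bilinear).
#'
#' @param stack A [projection_stack()] with at least 2 frames.
#' @param reference_index Index of the reference frame (default 1).
#' @param roi Optional registration window, a list with `rows = c(lo, hi)`
#'   and/or `cols = c(lo, hi)`.  The shift is estimated from this window
#'   only (the whole frame is still translated).  In staining time-lapses
#'   the window should cover static reference structures — the vial
#'   bottom and the punch silhouette — and exclude the moving cortical
#'   surface and staining front, which would otherwise bias the
#'   correlation peak.
#' @return A list with the registered `stack` and the recovered per-frame
#'   `shifts` (n-by-2 matrix, pixels; row shift, column shift).
#' @export
register_stack <- function(stack, reference_index = 1L, roi = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  if (length(stack$frames) < 2) stop("registration needs >= 2 frames")
  crop <- function(fr) {
    if (is.null(roi)) return(fr)
    r <- if (is.null(roi$rows)) c(1, nrow(fr)) else roi$rows
    c <- if (is.null(roi$cols)) c(1, ncol(fr)) else roi$cols
    fr[r[1]:r[2], c[1]:c[2], drop = FALSE]
  }
  ref <- crop(stack$frames[[reference_index]])
  shifts <- matrix(0, length(stack$frames), 2,
                   dimnames = list(NULL, c("row", "col")))
  frames <- stack$frames
  for (i in seq_along(frames)) {
    if (i == reference_index) next
    s <- .cc_shift(ref, crop(frames[[i]]))
    shifts[i, ] <- s
    frames[[i]] <- .translate(frames[[i]], s[1], s[2])
  }
  list(stack = projection_stack(frames, stack$timestamps, stack$pixel_size),
       shifts = shifts)
}

#' Flat-field correction of the cone-beam illumination bias
#'
#' A per-pixel median image of projections 2 to 5 is computed, a quadratic
#' surface `Z(x, y) = b5 x^2 + b4 y^2 + b3 x + b2 y + b1` is fitted to its
#' logarithm, and every frame is divided by `exp(Z)` and multiplied by
#' `max(exp(Z))`, removing the multiplicative radial intensity bias of the
#' cone-shaped beam.
#'
#' @param stack A [projection_stack()] with at least 5 frames.
#' @return The corrected [projection_stack()], with the fitted log-bias
#'   surface attached as attribute `"Z"`.
#' @export
flatfield_correct <- function(stack) {
  stopifnot(inherits(stack, "projection_stack"))
  if (length(stack$frames) < 5)
    stop("flat-field correction requires >= 5 frames")
  med <- apply(simplify2array(stack$frames[2:5]), c(1, 2), stats::median)
  if (any(med <= 0)) {
    bad <- which(med <= 0, arr.ind = TRUE)[1, ]
    stop("log-domain error: nonpositive median intensity at pixel (",
         bad[1], ", ", bad[2], ")")
  }
  nr <- nrow(med); nc <- ncol(med)
  g <- expand.grid(y = seq_len(nr), x = seq_len(nc))
  df <- data.frame(z = log(as.vector(med)), x = g$x, y = g$y)
  # Iteratively trimmed fit: pixels occluded by the sample (darker) or by
  # less-absorbing unstained tissue (brighter) deviate from the smooth
  # illumination surface seen through the uniform solution; trimming
  # outliers on both sides converges on the solution-dominated pixel set,
  # from which the quadratic extrapolates across the sample footprint.
  keep <- rep(TRUE, nrow(df))
  for (it in 1:10) {
    fit <- stats::lm(z ~ I(x^2) + I(y^2) + x + y, data = df,
                     subset = keep)
    res <- df$z - stats::predict(fit, df)
    s <- max(stats::mad(res[keep]), 1e-4)
    keep_new <- abs(res) < 2.5 * s
    if (all(keep_new == keep)) break
    keep <- keep_new
  }
  Z <- matrix(stats::predict(fit, df), nr, nc)
  corr <- exp(max(Z)) / exp(Z)
  frames <- lapply(stack$frames, function(fr) fr * corr)
  out <- projection_stack(frames, stack$timestamps, stack$pixel_size)
  attr(out, "Z") <- Z
  out
}

#' Extract a raw intensity profile along a cortical cross-section
#'
#' Samples the transmitted intensity `w(x, t)` along the cross-section
#' axis at one-pixel pitch, averaging over `half_width` pixels on either
#' side perpendicular to the axis.  Depth 0 is the cross-section origin;
#' negative depths sample the solution above the surface.
#'
#' @param stack A registered, flat-field corrected [projection_stack()].
#' @param cs A [cross_section()].
#' @return An [intensity_profile()] at stage `raw_w`.
#' @export
extract_profile <- function(stack, cs) {
  stopifnot(inherits(stack, "projection_stack"), inherits(cs, "cross_section"))
  px <- stack$pixel_size
  depth <- seq(-round(cs$solution_extent / px),
               round(cs$depth_extent / px)) * px
  steps <- depth / px
  perp <- c(-cs$direction[2], cs$direction[1])
  offs <- seq(-cs$half_width, cs$half_width)
  rows <- outer(steps, offs, function(s, o)
    cs$origin[1] + s * cs$direction[1] + o * perp[1])
  cols <- outer(steps, offs, function(s, o)
    cs$origin[2] + s * cs$direction[2] + o * perp[2])
  d <- dim(stack$frames[[1]])
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2])
    stop("geometry error: cross-section footprint outside the image")
  vals <- vapply(stack$frames, function(fr)
    rowMeans(matrix(.bilinear(fr, as.vector(rows), as.vector(cols)),
                    nrow = length(steps))),
    numeric(length(steps)))
  intensity_profile(depth, stack$timestamps, vals, stage = "raw_w")
}

#' Convert transmitted intensity to absorbance
#'
#' `u(x, t) = detector_full_scale - w(x, t)`.
#'
#' @param profile An [intensity_profile()] at stage `raw_w`.
#' @param detector_full_scale Detector full scale, a.u. (default 10000).
#' @return An [intensity_profile()] at stage `absorbance_u`.
#' @export
to_absorbance <- function(profile, detector_full_scale = 10000) {
  .check_stage(profile, "raw_w")
  intensity_profile(profile$depth, profile$time,
                    detector_full_scale - profile$values,
                    stage = "absorbance_u")
}

#' Baseline-correct an absorbance profile
#'
#' The per-time baseline `b(t)` is the mean absorbance over the solution
#' window (default -150 to -50 um from the surface); the corrected profile
#' is `u_b(x, t) = u(x, t) - b(t) - median_t(b)`.
#'
#' @param profile An [intensity_profile()] at stage `absorbance_u`.
#' @param params A [standardization_params()].
#' @return An [intensity_profile()] at stage `baseline_corrected_ub`, with
#'   the baseline series attached as attribute `"baseline"`.
#' @export
baseline_correct <- function(profile, params = standardization_params()) {
  .check_stage(profile, "absorbance_u")
  win <- profile$depth >= params$baseline_window[1] &
    profile$depth <= params$baseline_window[2]
  if (!any(win)) stop("window error: empty baseline window on this grid")
  b_t <- colMeans(profile$values[win, , drop = FALSE])
  ub <- sweep(profile$values, 2, b_t) - stats::median(b_t)
  out <- intensity_profile(profile$depth, profile$time, ub,
                           stage = "baseline_corrected_ub")
  attr(out, "baseline") <- b_t
  out
}

#' Standardize a baseline-corrected absorbance profile
#'
#' Affine rescaling anchored so that the concentration-absorbance relation
#' passes through the origin and saturated 2% OsO4 staining sits near 0.9.
#' With `bbar` the mean of `u_b` over the window `[-0.200, 0]` mm across
#' all times, the map is
#' `u_min = bbar - ((1 - 0.9)/0.9) (m - bbar)`,
#' `u_ref = u_min - a (m - u_min)`, `u_norm = (1 + a) (m - u_min)`,
#' `uhat = (u_b - u_ref) / u_norm`.
#'
#' @param profile An [intensity_profile()] at stage
#'   `baseline_corrected_ub`.
#' @param params A [standardization_params()].
#' @return An [intensity_profile()] at stage `standardized_uhat`; the
#'   intermediates are attached as attribute `"standardization"`.
#' @export
standardize_profile <- function(profile, params = standardization_params()) {
  .check_stage(profile, "baseline_corrected_ub")
  win <- profile$depth >= params$b_window[1] &
    profile$depth <= params$b_window[2]
  if (!any(win)) stop("window error: empty b-bar window on this grid")
  bbar <- mean(profile$values[win, , drop = FALSE])
  u_min <- bbar - ((1 - 0.9) / 0.9) * (params$m - bbar)
  u_ref <- u_min - params$a * (params$m - u_min)
  u_norm <- (1 + params$a) * (params$m - u_min)
  if (u_norm <= 0)
    stop("degenerate-standardization error: u_norm <= 0")
  uhat <- (profile$values - u_ref) / u_norm
  out <- intensity_profile(profile$depth, profile$time, uhat,
                           stage = "standardized_uhat")
  attr(out, "standardization") <-
    list(bbar = bbar, u_min = u_min, u_ref = u_ref, u_norm = u_norm)
  sol <- profile$depth < -0.05
  if (any(sol)) {
    u_sol <- (10 * (1 + params$a) - 9) / (10 * (1 + params$a))
    if (abs(mean(uhat[sol, ]) - u_sol) > 0.15)
      warning("solution region deviates from the expected standardized ",
              "level by more than 0.15")
  }
  out
}

#' Track the sample height through a projection stack
#'
#' Finds the cortical surface row in every frame as the maximum vertical
#' intensity gradient within a search band (columns averaged over a
#' horizontal band across the sample), smooths the detected rows with a
#' 5-frame running mean, and converts the distance to a fixed reference
#' row (the vial bottom) into a height series and percent change relative
#' to the first frame.
#'
#' @param stack A [projection_stack()].
#' @param search_rows Row interval `c(from, to)` to search for the surface;
#'   defaults to the full frame height.
#' @param band_cols Column interval averaged before edge detection;
#'   defaults to the middle third of the frame.
#' @param reference_row Vial-bottom reference row; defaults to the last row.
#' @param smooth Running-mean window (frames) applied to the detected rows.
#' @return A list with `height` (mm), `percent_change`, `surface_row`
#'   (smoothed, fractional) and `time` (min).  Frames without a detectable
#'   surface yield `NA` with a warning.
#' @export
track_height <- function(stack, search_rows = NULL, band_cols = NULL,
                         reference_row = NULL, smooth = 5L) {
  stopifnot(inherits(stack, "projection_stack"))
  d <- dim(stack$frames[[1]])
  if (is.null(search_rows)) search_rows <- c(2L, d[1] - 1L)
  if (is.null(band_cols))
    band_cols <- round(c(d[2] / 3, 2 * d[2] / 3))
  if (is.null(reference_row)) reference_row <- d[1]
  rows <- vapply(stack$frames, function(fr) {
    prof <- rowMeans(fr[, band_cols[1]:band_cols[2], drop = FALSE])
    # the surface is a bright-solution to dark-tissue transition, i.e. the
    # steepest intensity drop going down; the staining front below it has
    # the opposite sign and is thereby excluded
    grad <- diff(prof)
    idx <- seq(search_rows[1], search_rows[2] - 1)
    gband <- grad[idx]
    if (!any(is.finite(gband)) || min(gband) >= 0) return(NA_real_)
    idx[which.min(gband)] + 0.5
  }, numeric(1))
  if (anyNA(rows))
    warning("surface not detectable in ", sum(is.na(rows)), " frame(s)")
  if (smooth > 1) {
    k <- as.integer(smooth)
    sm <- stats::filter(rows, rep(1 / k, k), sides = 2)
    # fall back to raw detections where the running mean is undefined
    rows <- ifelse(is.na(sm), rows, as.numeric(sm))
  }
  height <- (reference_row - rows) * stack$pixel_size
  pct <- (height - height[1]) / height[1] * 100
  list(height = height, percent_change = pct, surface_row = rows,
       time = stack$timestamps)
}
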