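# shared builders for the test suite; all fixtures are generated in code

erfc_ <- function(z) 2 * stats::pnorm(-sqrt(2) * z)

# the study-condition ground truth used by the recovery tests: geometry and
# growth from the recorded experiment, kinetics at the package defaults
recovery_truth <- function(noise_sigma = 0, seed = 1L) {
  synth_ground_truth(
    kinetics = kinetic_params(),
    geometry = geometry_model(R = 4, H = 0.4, D = 25, L = 1.5),
    growth = growth_model(),
    noise_sigma = noise_sigma, seed = seed, sim_nodes = 151L)
}

recovery_grids <- function() {
  list(depth = seq(-0.2, 1.4, by = 0.02), time = seq(0, 1200, by = 40))
}

truth_vector <- function(truth = recovery_truth()) {
  kp <- truth$kinetics
  c(De = kp$De, kon = kp$kon, kunmask = kp$kunmask,
    S0 = kp$S0, M0 = kp$M0, H = truth$geometry$H)
}

fit_vector <- function(fit) {
  c(De = fit$params$De, kon = fit$params$kon,
    kunmask = fit$params$kunmask, S0 = fit$params$S0,
    M0 = fit$params$M0, H = fit$H)
}

# full projection-stack study: generate, preprocess, extract
stack_study <- function(seed = 7L, noise_sigma = 0, shifts = NULL,
                        bias_coeffs = NULL, n_frames = 40L) {
  tru <- synth_ground_truth(
    kinetics = kinetic_params(), geometry = geometry_model(),
    growth = growth_model(), shifts = shifts,
    noise_sigma = noise_sigma, seed = seed)
  if (!is.null(bias_coeffs)) tru$bias_coeffs <- bias_coeffs
  generate_projection_stack(tru, acquisition_spec(n_frames = n_frames))
}

# the preprocessing chain in its standard order
preprocess_chain <- function(syn, depth_extent = 0.7,
                             solution_extent = 0.25) {
  ff <- flatfield_correct(syn$stack)
  reg <- register_stack(ff)
  r0 <- tail(syn$render$surface_rows, 1)
  cs <- cross_section(origin = c(r0, syn$render$center_col),
                      depth_extent = depth_extent,
                      solution_extent = solution_extent)
  uhat <- standardize_profile(baseline_correct(to_absorbance(
    extract_profile(reg$stack, cs))))
  list(uhat = uhat, reg = reg, origin_row = r0)
}

# rendered ground-truth line resampled on the extracted profile's grid
rendered_truth <- function(syn, profile, origin_row) {
  rows <- origin_row + round(profile$depth / syn$stack$pixel_size)
  syn$line_uhat[rows, , drop = FALSE]
}
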