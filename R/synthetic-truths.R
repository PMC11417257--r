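# Ground-truth parameter sets for the synthetic-data generators. Each truth
# object is a validated list; generators are pure functions of (truth, seed).

#' Ground truth for a synthetic cuticle topography image
#'
#' Describes a stepped ("staircase") cuticle surface: terraces of fixed length
#' along the fast-scan axis separated by rises drawn from a normal
#' distribution, plus a tilt plane, correlated Gaussian surface roughness and
#' optional debris bumps.
#'
#' @param step_height_mean Mean cuticle step (rise) height, nm. Must be > 0.
#' @param step_height_sd Standard deviation of individual rises, nm.
#' @param terrace_length Terrace (exposed scale) length, um. Must be > 0.
#' @param roughness_sd Standard deviation of the surface roughness field, nm.
#' @param roughness_correlation_length Lateral correlation length of the
#'   roughness field, um. `0` gives white noise.
#' @param tilt Sample tilt along the fast-scan axis, nm per um.
#' @param debris_density Expected debris bumps per um^2.
#' @param debris_height Height of a debris bump, nm.
#' @return An object of class `topo_truth`.
#' @export
#' @examples
#' topo_truth(step_height_mean = 430.2, step_height_sd = 52.7)
topo_truth <- function(step_height_mean = 430.2, step_height_sd = 52.7,
                       terrace_length = 3.5, roughness_sd = 6,
                       roughness_correlation_length = 0.3, tilt = 0,
                       debris_density = 0, debris_height = 80) {
  check_scalar(step_height_mean, "step_height_mean", lower = 0, strict_lower = TRUE)
  check_scalar(step_height_sd, "step_height_sd", lower = 0)
  check_scalar(terrace_length, "terrace_length", lower = 0, strict_lower = TRUE)
  check_scalar(roughness_sd, "roughness_sd", lower = 0)
  check_scalar(roughness_correlation_length, "roughness_correlation_length", lower = 0)
  check_scalar(tilt, "tilt")
  check_scalar(debris_density, "debris_density", lower = 0)
  check_scalar(debris_height, "debris_height", lower = 0)
  structure(
    list(step_height_mean = step_height_mean, step_height_sd = step_height_sd,
         terrace_length = terrace_length, roughness_sd = roughness_sd,
         roughness_correlation_length = roughness_correlation_length,
         tilt = tilt, debris_density = debris_density,
         debris_height = debris_height),
    class = "topo_truth")
}

#' Ground truth for a synthetic force-distance curve
#'
#' The measured contact slope follows the series-spring relation
#' `s = k * k_s / (k + k_s)` for cantilever constant `k` and sample stiffness
#' `k_s`; `sample_stiffness = Inf` models a rigid surface (slope `k`).
#'
#' @param sample_stiffness Sample stiffness, nN/nm. May be `Inf` (rigid).
#' @param spring_constant Cantilever force constant, nN/nm.
#' @param attraction_depth Snap-in dip depth on approach, nN (>= 0).
#' @param adhesion_depth Pull-off dip depth on retract, nN (>= 0). Independent
#'   of `attraction_depth`; no ordering is imposed.
#' @param setpoint Maximum load force, nN. Must be in (0, 10].
#' @param noise_sd Gaussian force noise, nN.
#' @return An object of class `fd_truth`.
#' @export
#' @examples
#' fd_truth(sample_stiffness = 0.88, spring_constant = 0.2)
fd_truth <- function(sample_stiffness = 0.88, spring_constant = 0.2,
                     attraction_depth = 0.591, adhesion_depth = 1.2,
                     setpoint = 8, noise_sd = 0.02) {
  check_scalar(sample_stiffness, "sample_stiffness", lower = 0,
               strict_lower = TRUE, allow_inf = TRUE)
  check_scalar(spring_constant, "spring_constant", lower = 0, strict_lower = TRUE)
  check_scalar(attraction_depth, "attraction_depth", lower = 0)
  check_scalar(adhesion_depth, "adhesion_depth", lower = 0)
  check_scalar(setpoint, "setpoint", lower = 0, upper = 10, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(
    list(sample_stiffness = sample_stiffness, spring_constant = spring_constant,
         attraction_depth = attraction_depth, adhesion_depth = adhesion_depth,
         setpoint = setpoint, noise_sd = noise_sd),
    class = "fd_truth")
}

#' Expected contact slope of a force-distance curve truth
#'
#' Series-spring relation between cantilever and sample.
#'
#' @param truth An [fd_truth()] object.
#' @return Slope in nN/nm.
#' @export
fd_contact_slope <- function(truth) {
  stopifnot(inherits(truth, "fd_truth"))
  k <- truth$spring_constant
  ks <- truth$sample_stiffness
  if (is.infinite(ks)) k else k * ks / (k + ks)
}

#' Ground truth for a synthetic tensile stress-strain curve
#'
#' Three-region keratin-fiber model: a Hookean pre-yield segment of slope
#' `elastic_modulus`, a near-flat yield plateau (slope fixed at 2 % of the
#' elastic modulus, so segmentation must cope with near-flat rather than
#' exactly flat data), and a re-stiffening post-yield segment up to fracture.
#'
#' @param elastic_modulus Pre-yield slope, MPa.
#' @param yield_strain Strain at the pre-yield/yield breakpoint (fraction).
#' @param post_yield_onset_strain Strain at the yield/post-yield breakpoint.
#' @param post_yield_modulus Post-yield slope, MPa.
#' @param fracture_strain Strain at fracture (fraction); the record ends here.
#' @param diameter Fiber diameter, um.
#' @param noise_sd Gaussian stress noise, MPa.
#' @return An object of class `tensile_truth`.
#' @export
#' @examples
#' tensile_truth(elastic_modulus = 3000, fracture_strain = 0.47)
tensile_truth <- function(elastic_modulus = 3000, yield_strain = 0.03,
                          post_yield_onset_strain = 0.25,
                          post_yield_modulus = 700, fracture_strain = 0.47,
                          diameter = 80, noise_sd = 2) {
  check_scalar(elastic_modulus, "elastic_modulus", lower = 0, strict_lower = TRUE)
  check_scalar(yield_strain, "yield_strain", lower = 0, strict_lower = TRUE)
  check_scalar(post_yield_onset_strain, "post_yield_onset_strain", lower = 0)
  check_scalar(post_yield_modulus, "post_yield_modulus", lower = 0, strict_lower = TRUE)
  check_scalar(fracture_strain, "fracture_strain", lower = 0)
  check_scalar(diameter, "diameter", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (!(yield_strain < post_yield_onset_strain &&
        post_yield_onset_strain < fracture_strain)) {
    stop("require 0 < yield_strain < post_yield_onset_strain < fracture_strain",
         call. = FALSE)
  }
  structure(
    list(elastic_modulus = elastic_modulus, yield_strain = yield_strain,
         post_yield_onset_strain = post_yield_onset_strain,
         post_yield_modulus = post_yield_modulus,
         fracture_strain = fracture_strain, diameter = diameter,
         noise_sd = noise_sd),
    class = "tensile_truth")
}

# slope of the yield plateau relative to the elastic modulus
YIELD_PLATEAU_FRACTION <- 0.02

#' Noiseless stress at given strains for a tensile truth
#'
#' Closed-form evaluation of the three-region piecewise-linear model; used
#' both by the generator and as the reference in recovery tests.
#'
#' @param truth A [tensile_truth()] object.
#' @param strain Strain values (fractions).
#' @return Stress in MPa.
#' @export
tensile_model_stress <- function(truth, strain) {
  stopifnot(inherits(truth, "tensile_truth"))
  e <- truth$elastic_modulus
  y <- truth$yield_strain
  o <- truth$post_yield_onset_strain
  p <- truth$post_yield_modulus
  plateau <- YIELD_PLATEAU_FRACTION * e
  s_y <- e * y
  s_o <- s_y + plateau * (o - y)
  ifelse(strain <= y, e * strain,
         ifelse(strain <= o, s_y + plateau * (strain - y),
                s_o + p * (strain - o)))
}

#' Ground truth for a synthetic FT-IR transmittance spectrum
#'
#' A spectrum is modeled as a ~100 %T baseline (optionally sloped) with
#' Gaussian dips at the configured band centers, plus Gaussian noise, clipped
#' below at 0 %T.
#'
#' @param bands Data frame with columns `name`, `center` (cm^-1), `depth`
#'   (%T, in \[0, 100\]) and `width` (Gaussian sigma, cm^-1, > 0).
#' @param baseline_slope Baseline slope, %T per cm^-1.
#' @param noise_sd Gaussian transmittance noise, %T.
#' @return An object of class `spectrum_truth`.
#' @export
#' @examples
#' spectrum_truth(keratin_bands("control"))
spectrum_truth <- function(bands, baseline_slope = 0, noise_sd = 0.3) {
  if (!is.data.frame(bands) ||
      !all(c("name", "center", "depth", "width") %in% names(bands))) {
    stop("`bands` must be a data frame with name/center/depth/width columns",
         call. = FALSE)
  }
  if (any(bands$depth < 0 | bands$depth > 100)) {
    stop("band depths must lie in [0, 100] %T", call. = FALSE)
  }
  if (any(bands$width <= 0)) stop("band widths must be > 0", call. = FALSE)
  check_scalar(baseline_slope, "baseline_slope")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(
    list(bands = bands, baseline_slope = baseline_slope, noise_sd = noise_sd),
    class = "spectrum_truth")
}

#' Keratin band sets for control-like and dyed-like spectra
#'
#' Band centers sit inside the standard keratin windows: amide I
#' (1600-1690 cm^-1), amide II (1480-1575), amide III (1229-1301), amide B
#' (near 3066), lipid (near 3135), water (broad, near 3277) and the cysteic
#' acid S=O band (1035.9). Dyed-like sets add the 1575 cm^-1 NH2 scissoring
#' band that is absent from control hair, reduce the water and cysteic acid
#' depths and deepen the amide bands.
#'
#' @param kind `"control"` or `"dyed"`.
#' @param water_depth Water band depth, %T.
#' @param cysteic_depth Cysteic acid band depth, %T.
#' @param nh2_depth NH2 (1575 cm^-1) band depth, %T; only used for `"dyed"`.
#' @param amide_scale Multiplier on the three amide band depths.
#' @return Data frame of band parameters suitable for [spectrum_truth()].
#' @export
keratin_bands <- function(kind = c("control", "dyed"), water_depth = 15,
                          cysteic_depth = 3, nh2_depth = 3, amide_scale = 1) {
  kind <- match.arg(kind)
  b <- data.frame(
    name   = c("amide_I", "amide_II", "amide_III", "amide_B",
               "lipid", "water", "cysteic_acid"),
    center = c(1650, 1520, 1245, 3066, 3135, 3277, 1035.9),
    depth  = c(40 * amide_scale, 30 * amide_scale, 12 * amide_scale,
               8, 5, water_depth, cysteic_depth),
    width  = c(18, 14, 16, 12, 8, 40, 8),
    stringsAsFactors = FALSE)
  if (kind == "dyed") {
    b <- rbind(b, data.frame(name = "nh2", center = 1575, depth = nh2_depth,
                             width = 8, stringsAsFactors = FALSE))
  }
  b
}
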