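# Shared fixture builders. Everything is generated in code; noiseless
# variants let tests assert closed-form values exactly.

noiseless_topo <- function(...) {
  topo_truth(step_height_sd = 0, roughness_sd = 0, tilt = 0,
             debris_density = 0, ...)
}

noiseless_fd <- function(...) fd_truth(noise_sd = 0, ...)

noiseless_tensile <- function(...) tensile_truth(noise_sd = 0, ...)

flat_spectrum_truth <- function(noise_sd = 0) {
  spectrum_truth(data.frame(name = character(0), center = numeric(0),
                            depth = numeric(0), width = numeric(0)),
                 baseline_slope = 0, noise_sd = noise_sd)
}

single_band_truth <- function(center = 1650, depth = 20, width = 15,
                              noise_sd = 0, baseline_slope = 0) {
  spectrum_truth(data.frame(name = "test", center = center, depth = depth,
                            width = width),
                 baseline_slope = baseline_slope, noise_sd = noise_sd)
}

# independent pooled Student's t oracle (hand formula)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p)
}

tiny_cohort_config <- function(root, seed = 42L, n_fibers = 3L) {
  mk_group <- function(dye, step, slope, attr_, water, kind) {
    cohort_group(
      dye_count = dye, n_fibers = n_fibers,
      topo = topo_truth(step_height_mean = step, step_height_sd = 20,
                        roughness_sd = 5, tilt = 0, debris_density = 0),
      fd = fd_truth(sample_stiffness = 0.2 * slope / (0.2 - slope),
                    attraction_depth = attr_),
      tensile = tensile_truth(),
      spectrum = spectrum_truth(keratin_bands(kind, water_depth = water)))
  }
  cohort_config(
    list(mk_group(0L, 430.2, 0.163, 0.591, 15, "control"),
         mk_group(1L, 343.3, 0.163, 0.367, 9, "dyed")),
    seed = seed, root = root,
    topo_size = c(48L, 96L), topo_pixel_size = 15 / 95,
    fd_points = 250L, tensile_points = 300L)
}
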