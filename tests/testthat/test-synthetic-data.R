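# Generators: determinism, noiseless closed-form limits, and the on-disk
# cohort contract.

test_that("noiseless topography is an exact staircase with the configured rise", {
  truth <- noiseless_topo(step_height_mean = 430.2, terrace_length = 3.5)
  img <- gen_topography(truth, size = c(32L, 128L), pixel_size = 15 / 127,
                        seed = 1)
  prof <- img$heights[7, ]
  rises <- diff(prof)
  jumps <- rises[rises != 0]
  expect_true(all(abs(jumps - 430.2) < 1e-12))
  expect_identical(length(jumps), 4L)           # 15 um field / 3.5 um terraces
  # all rows identical: the staircase runs along the column axis
  expect_true(all(img$heights == matrix(prof, 32, 128, byrow = TRUE)))
})

test_that("a terrace longer than the field of view yields a step-free image", {
  truth <- noiseless_topo(terrace_length = 50)
  img <- gen_topography(truth, size = c(16L, 64L), pixel_size = 0.2, seed = 1)
  expect_true(all(img$heights == 0))
  rough <- topo_truth(step_height_sd = 0, roughness_sd = 3, tilt = 0,
                      debris_density = 0, terrace_length = 50)
  img2 <- gen_topography(rough, size = c(16L, 64L), pixel_size = 0.2, seed = 1)
  expect_true(stats::sd(img2$heights) > 0)       # roughness only
  expect_lt(max(abs(img2$heights)), 30)          # no 400 nm steps anywhere
})

test_that("generators are bit-identical under a fixed seed and leave the RNG alone", {
  truth <- topo_truth(roughness_sd = 8, debris_density = 0.05)
  a <- gen_topography(truth, c(24L, 24L), 0.5, seed = 7)
  b <- gen_topography(truth, c(24L, 24L), 0.5, seed = 7)
  expect_identical(a$heights, b$heights)
  c_ <- gen_topography(truth, c(24L, 24L), 0.5, seed = 8)
  expect_false(identical(a$heights, c_$heights))

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_fd_curve(fd_truth(), 100, seed = 1))
  after <- rnorm(1)
  expect_identical(before, after)

  f1 <- gen_fd_curve(fd_truth(), 120, seed = 5)
  f2 <- gen_fd_curve(fd_truth(), 120, seed = 5)
  expect_identical(f1$approach, f2$approach)
  s1 <- gen_spectrum(spectrum_truth(keratin_bands("control")), seed = 3)
  s2 <- gen_spectrum(spectrum_truth(keratin_bands("control")), seed = 3)
  expect_identical(s1$transmittance, s2$transmittance)
})

test_that("FD contact slope follows the series-spring relation", {
  rigid <- gen_fd_curve(noiseless_fd(sample_stiffness = Inf), 200, seed = 1)
  app <- rigid$approach
  top <- app[app[, 2] > 1, ]                    # well inside contact
  fit <- lm(top[, 2] ~ top[, 1])
  expect_equal(unname(coef(fit)[2]), 0.2, tolerance = 1e-9)

  soft <- gen_fd_curve(noiseless_fd(sample_stiffness = 0.88), 200, seed = 1)
  app <- soft$approach
  top <- app[app[, 2] > 1, ]
  fit <- lm(top[, 2] ~ top[, 1])
  expect_equal(unname(coef(fit)[2]), 0.2 * 0.88 / 1.08, tolerance = 1e-9)
})

test_that("noiseless FD branches hit their configured extremes exactly", {
  crv <- gen_fd_curve(noiseless_fd(attraction_depth = 0.3, adhesion_depth = 1.5),
                      300, seed = 1)
  expect_equal(min(crv$approach[, 2]), -0.3, tolerance = 1e-12)
  expect_equal(min(crv$retract[, 2]), -1.5, tolerance = 1e-12)
  expect_equal(max(crv$approach[, 2]), 8, tolerance = 1e-12)  # setpoint

  none <- gen_fd_curve(noiseless_fd(attraction_depth = 0, adhesion_depth = 0),
                       300, seed = 1)
  expect_identical(min(none$approach[, 2]), 0)
  expect_identical(min(none$retract[, 2]), 0)
})

test_that("noiseless tensile curve equals the piecewise model; fracture ends the record", {
  truth <- noiseless_tensile(elastic_modulus = 3000, yield_strain = 0.03,
                             fracture_strain = 0.47)
  crv <- gen_tensile_curve(truth, n_points = 471, seed = 1)
  expect_equal(crv$stress[crv$strain == 0.03], 90, tolerance = 1e-9)
  expect_equal(max(crv$strain), 0.47, tolerance = 1e-12)
  expect_equal(crv$stress, tensile_model_stress(truth, crv$strain),
               tolerance = 1e-12)

  n1 <- gen_tensile_curve(tensile_truth(noise_sd = 2), 300, seed = 1)
  n2 <- gen_tensile_curve(tensile_truth(noise_sd = 2), 300, seed = 2)
  mdl <- tensile_model_stress(tensile_truth(), n1$strain)
  expect_identical(n1$strain, n2$strain)         # same underlying grid
  expect_false(identical(n1$stress, n2$stress))  # different residuals
  expect_lt(abs(mean(n1$stress - mdl)), 0.5)     # both scatter around the model
  expect_lt(abs(mean(n2$stress - mdl)), 0.5)
})

test_that("spectrum generator: flat limit, single dip, and band windows", {
  flat <- gen_spectrum(flat_spectrum_truth(), seed = 1)
  expect_true(all(flat$transmittance == 100))

  one <- gen_spectrum(single_band_truth(1650, 20, 15), seed = 1)
  i <- which.min(one$transmittance)
  expect_lte(abs(one$wavenumbers[i] - 1650), 4)   # within one resolution step
  expect_equal(min(one$transmittance), 80, tolerance = 0.02)

  ker <- gen_spectrum(spectrum_truth(keratin_bands("control"), noise_sd = 0),
                      seed = 1)
  in_window <- function(lo, hi) {
    idx <- ker$wavenumbers >= lo & ker$wavenumbers <= hi
    min(ker$transmittance[idx]) < 95
  }
  expect_true(in_window(1600, 1690))   # amide I
  expect_true(in_window(1480, 1575))   # amide II

  expect_warning(
    gen_spectrum(single_band_truth(center = 5000), seed = 1),
    "outside range")
})

test_that("invalid generator parameters are rejected", {
  expect_error(gen_topography(topo_truth(), c(4L, 4L), 0.1, seed = 1), ">= 16")
  expect_error(gen_topography(topo_truth(), c(32L, 32L), -1, seed = 1),
               "pixel_size")
  expect_error(topo_truth(step_height_mean = -5), "step_height_mean")
  expect_error(fd_truth(setpoint = 12), "setpoint")
  expect_error(gen_fd_curve(fd_truth(), 10, seed = 1), ">= 50")
  expect_error(tensile_truth(yield_strain = 0.3, post_yield_onset_strain = 0.2),
               "yield_strain")
  expect_error(gen_tensile_curve(tensile_truth(), 50, seed = 1), ">= 100")
  expect_error(gen_spectrum(single_band_truth(), wavenumber_range = c(2000, 1000),
                            seed = 1), "min < max")
})

test_that("gen_cohort writes the full layout and a reproducible manifest", {
  root1 <- withr::local_tempdir()
  root2 <- withr::local_tempdir()
  m1 <- gen_cohort(tiny_cohort_config(root1))
  m2 <- gen_cohort(tiny_cohort_config(root2))

  expect_identical(nrow(m1), 6L)                     # 2 groups x 3 fibers
  expect_setequal(list.dirs(root1, recursive = FALSE, full.names = FALSE),
                  c("0", "1"))
  files <- list.files(file.path(root1, "0"))
  expect_identical(length(files), 12L)               # 3 fibers x 4 modalities
  expect_true(all(file.exists(file.path(root1, m1$topo_file))))

  # byte-identical manifests across runs (paths are relative)
  expect_identical(readLines(file.path(root1, "manifest.csv")),
                   readLines(file.path(root2, "manifest.csv")))

  # parameter round-trip: configured truths recorded exactly
  expect_identical(unique(m1$topo_step_height_mean[m1$dye_count == 0]), 430.2)
  expect_identical(unique(m1$topo_step_height_mean[m1$dye_count == 1]), 343.3)
  expect_identical(unique(m1$truth_attraction[m1$dye_count == 1]), 0.367)
  expect_equal(unique(m1$truth_stiffness[m1$dye_count == 0]), 0.163,
               tolerance = 1e-12)
})
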