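# Tensile analysis: stress conversion, three-region segmentation, features.

test_that("stress conversion implements sigma = F / A with unit round-trip", {
  expect_identical(compute_stress(0, diameter = 80), 0)
  # F = 100 mN, d = 80 um -> A = 5026.55 um^2, sigma = 19.89 MPa
  expect_equal(compute_stress(100, diameter = 80), 19.8944, tolerance = 1e-4)

  set.seed(1)
  f <- runif(50, 0, 200)
  sigma <- compute_stress(f, diameter = 73)
  back <- sigma * pi * (73 / 2)^2 * 1e-3
  expect_equal(back, f, tolerance = 1e-12)

  # doubling the diameter divides stress by 4 exactly
  expect_equal(compute_stress(f, diameter = 146) * 4,
               compute_stress(f, diameter = 73), tolerance = 1e-12)

  # 2 gf pre-tension = 19.613 mN, subtracted before conversion
  with_g <- compute_stress(100, diameter = 80, gauge_force_gf = 2)
  expect_equal(with_g, compute_stress(100 - 19.6133, diameter = 80),
               tolerance = 1e-4)
  expect_error(compute_stress(100, diameter = 0), "diameter")
})

test_that("noiseless segmentation recovers breakpoints and modulus exactly", {
  # 471 points over [0, 0.47] puts the true breakpoints on the strain grid
  truth <- noiseless_tensile(elastic_modulus = 3000, yield_strain = 0.03,
                             post_yield_onset_strain = 0.25,
                             fracture_strain = 0.47)
  crv <- gen_tensile_curve(truth, n_points = 471, seed = 1)
  seg <- segment_regions(crv)
  expect_false(seg$degenerate)
  expect_equal(seg$yield_bounds, c(0.03, 0.25), tolerance = 1e-9)
  expect_identical(which.min(abs(seg$slopes)), 2L)

  f <- tensile_features(crv)
  expect_equal(f$elastic_modulus, 3000, tolerance = 1e-6)
  expect_equal(f$yield_stress, 90, tolerance = 1e-9)
  expect_equal(f$fracture_strain, 0.47, tolerance = 1e-12)
  expect_equal(f$fracture_stress, tensile_model_stress(truth, 0.47),
               tolerance = 1e-9)
})

test_that("off-grid noiseless breakpoints are recovered within one grid spacing", {
  for (e in c(3000, 8700)) {   # spans the dose-response modulus range
    truth <- noiseless_tensile(elastic_modulus = e, yield_strain = 0.034,
                               post_yield_onset_strain = 0.23,
                               post_yield_modulus = 850,
                               fracture_strain = 0.52)
    crv <- gen_tensile_curve(truth, n_points = 400, seed = 1)
    px <- 0.52 / 399
    seg <- segment_regions(crv)
    expect_false(seg$degenerate)
    expect_lte(abs(seg$yield_bounds[1] - 0.034), px)
    expect_lte(abs(seg$yield_bounds[2] - 0.23), px)
  }
})

test_that("a purely linear record is flagged degenerate and treated as pre-yield", {
  strain <- seq(0, 0.4, length.out = 200)
  lin <- tensile_curve(strain, stress = 2500 * strain, diameter = 80)
  seg <- segment_regions(lin)
  expect_true(seg$degenerate)
  f <- tensile_features(lin)
  expect_true(f$degenerate)
  expect_equal(f$elastic_modulus, 2500, tolerance = 1e-9)

  set.seed(5)
  noisy_lin <- tensile_curve(strain, stress = 2500 * strain + rnorm(200, 0, 2),
                             diameter = 80)
  expect_true(segment_regions(noisy_lin)$degenerate)
})

test_that("noisy breakpoint recovery stays within one strain percent (median)", {
  errs <- t(sapply(1:20, function(i) {
    crv <- gen_tensile_curve(tensile_truth(), n_points = 400, seed = 500 + i)
    seg <- segment_regions(crv)
    abs(seg$yield_bounds - c(0.03, 0.25))
  }))
  expect_lt(median(errs[, 1]), 0.01)
  expect_lt(median(errs[, 2]), 0.01)
})

test_that("dyed-over-control fracture ordering survives extraction", {
  ctrl <- tensile_features(gen_tensile_curve(
    noiseless_tensile(fracture_strain = 0.47), 300, seed = 1))
  dyed <- tensile_features(gen_tensile_curve(
    noiseless_tensile(elastic_modulus = 8700, yield_strain = 0.0176,
                      post_yield_modulus = 880, fracture_strain = 0.52),
    300, seed = 1))
  expect_gt(dyed$fracture_strain, ctrl$fracture_strain)
  expect_gt(dyed$elastic_modulus, ctrl$elastic_modulus)
})

test_that("the optional terminal-drop detector truncates real-style traces", {
  strain <- seq(0, 0.5, length.out = 300)
  stress <- tensile_model_stress(tensile_truth(noise_sd = 0,
                                               fracture_strain = 0.51), strain)
  stress[strain > 0.47] <- 5   # post-break tail recorded by the instrument
  crv <- tensile_curve(strain, stress = stress, diameter = 80)
  f <- tensile_features(crv, drop_detect = TRUE)
  expect_lt(abs(f$fracture_strain - 0.47), 0.005)
})

test_that("segmentation preconditions are enforced", {
  short <- tensile_curve(seq(0, 0.4, length.out = 50),
                         stress = seq(0, 100, length.out = 50), diameter = 80)
  expect_error(segment_regions(short), ">= 100")
  narrow <- tensile_curve(seq(0, 0.05, length.out = 150),
                          stress = seq(0, 100, length.out = 150), diameter = 80)
  expect_error(segment_regions(narrow), "0.1")
})
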