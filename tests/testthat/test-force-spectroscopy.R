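# Force-distance analysis: baseline correction, snap-in/pull-off detection,
# stiffness fitting, composed feature extraction and its invariances.

shift_curve <- function(crv, offset = 0, slope = 0) {
  bump <- function(b) {
    b[, 2] <- b[, 2] + offset + slope * b[, 1]
    b
  }
  fd_curve(bump(crv$approach), bump(crv$retract), crv$spring_constant, crv$id)
}

test_that("baseline correction removes offsets and tilts", {
  crv <- gen_fd_curve(fd_truth(), 300, seed = 2)
  plain <- baseline_correct(crv)
  far <- plain$approach[plain$approach[, 1] < 20, 2]
  expect_lt(abs(mean(far)), 0.01)

  offs <- baseline_correct(shift_curve(crv, offset = 0.5))
  expect_equal(offs$approach[, 2], plain$approach[, 2], tolerance = 1e-9)

  tilted <- baseline_correct(shift_curve(crv, slope = 2e-3))
  far_fit <- lm(tilted$approach[tilted$approach[, 1] < 20, 2] ~
                  tilted$approach[tilted$approach[, 1] < 20, 1])
  expect_lt(abs(coef(far_fit)[2]), 1e-3)

  # an all-contact ramp has no identifiable non-contact region
  d <- seq(0, 100, length.out = 100)
  ramp <- fd_curve(cbind(d, 0.18 * d), cbind(rev(d), rev(0.18 * d)), 0.2)
  expect_error(baseline_correct(ramp), "non-contact")
})

test_that("snap-in and pull-off read their dips exactly in the noiseless limit", {
  crv <- baseline_correct(gen_fd_curve(
    noiseless_fd(attraction_depth = 0.3, adhesion_depth = 1.5), 300, seed = 1))
  snap <- detect_snap_in(crv)
  pull <- detect_pull_off(crv)
  expect_equal(snap$attraction, 0.3, tolerance = 1e-9)
  expect_true(snap$detected)
  expect_equal(pull$adhesion, 1.5, tolerance = 1e-9)
  expect_true(pull$detected)

  none <- baseline_correct(gen_fd_curve(
    fd_truth(attraction_depth = 0, adhesion_depth = 0, noise_sd = 0.02),
    300, seed = 1))
  s0 <- detect_snap_in(none)
  p0 <- detect_pull_off(none)
  expect_identical(s0$attraction, 0)
  expect_false(s0$detected)
  expect_identical(p0$adhesion, 0)
  expect_false(p0$detected)

  # adhesion < attraction is a valid, independent configuration
  swap <- fd_features(gen_fd_curve(
    noiseless_fd(attraction_depth = 1.0, adhesion_depth = 0.4), 300, seed = 1))
  expect_equal(swap$attraction, 1.0, tolerance = 1e-9)
  expect_equal(swap$adhesion, 0.4, tolerance = 1e-9)
})

test_that("stiffness fitting recovers the series-spring slope", {
  rigid <- fit_stiffness(baseline_correct(gen_fd_curve(
    noiseless_fd(sample_stiffness = Inf), 300, seed = 1)))
  expect_equal(rigid$stiffness, 0.2, tolerance = 1e-9)
  expect_identical(rigid$sample_stiffness, Inf)

  soft <- fit_stiffness(baseline_correct(gen_fd_curve(
    noiseless_fd(sample_stiffness = 0.88), 300, seed = 1)))
  expect_equal(soft$stiffness, 0.2 * 0.88 / 1.08, tolerance = 1e-9)
  expect_equal(soft$sample_stiffness, 0.88, tolerance = 1e-9)
  expect_gt(soft$r_squared, 0.999)

  noisy <- fit_stiffness(baseline_correct(gen_fd_curve(fd_truth(), 400,
                                                       seed = 3)))
  expect_equal(noisy$stiffness, 0.163, tolerance = 0.02)
})

test_that("feature extraction composes the detectors and enforces the contract", {
  truth <- fd_truth()
  f <- fd_features(gen_fd_curve(truth, 400, seed = 11))
  expect_equal(f$stiffness, 0.163, tolerance = 0.02)
  expect_equal(f$attraction, 0.591, tolerance = 0.06)
  expect_equal(f$adhesion, 1.2, tolerance = 0.06)

  exact <- fd_features(gen_fd_curve(noiseless_fd(), 300, seed = 1))
  expect_equal(exact$stiffness, 0.2 * 0.88 / 1.08, tolerance = 1e-9)
  expect_equal(exact$attraction, 0.591, tolerance = 1e-9)
  expect_equal(exact$adhesion, 1.2, tolerance = 1e-9)

  expect_error(fd_curve(cbind(c(1, 2, 2, 4:20), rnorm(20)),
                        cbind(20:1, rnorm(20)), 0.2),
               "monotone")
})

test_that("attraction depends only on approach; adhesion only on retract", {
  crv <- gen_fd_curve(fd_truth(), 300, seed = 4)
  base <- fd_features(crv)
  mangled_ret <- fd_curve(crv$approach,
                          cbind(crv$retract[, 1], crv$retract[, 2] * 0.5),
                          crv$spring_constant)
  mangled_app <- fd_curve(cbind(crv$approach[, 1],
                                pmin(crv$approach[, 2], 4)),
                          crv$retract, crv$spring_constant)
  expect_identical(fd_features(mangled_ret)$attraction, base$attraction)
  expect_identical(fd_features(mangled_app)$adhesion, base$adhesion)
})

test_that("constant force offsets change no feature", {
  crv <- gen_fd_curve(fd_truth(), 300, seed = 6)
  base <- fd_features(crv)
  shifted <- fd_features(shift_curve(crv, offset = 0.7))
  expect_equal(shifted$stiffness, base$stiffness, tolerance = 1e-9)
  expect_equal(shifted$attraction, base$attraction, tolerance = 1e-9)
  expect_equal(shifted$adhesion, base$adhesion, tolerance = 1e-9)
})

test_that("extracted stiffness respects the series-spring bound over many curves", {
  set.seed(42)
  for (i in 1:25) {
    ks <- runif(1, 0.2, 3)
    f <- fd_features(gen_fd_curve(fd_truth(sample_stiffness = ks), 300,
                                  seed = 100 + i))
    expect_lte(f$stiffness, 0.2 + 1e-6)
  }
})
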