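# Topography metrology: flattening, profiles, step detection, Sa/Sz, crops.

brute_sa_sz <- function(z) {
  # direct evaluation of the definitions, independent of roughness()
  list(Sa = sum(abs(z - sum(z) / length(z))) / length(z),
       Sz = max(z) - min(z))
}

test_that("flattening removes fitted surfaces exactly and is idempotent", {
  r <- matrix(seq_len(20), 20, 30)
  c_ <- matrix(seq_len(30), 20, 30, byrow = TRUE)
  plane <- topography_image(5 + 2 * r - 3 * c_, pixel_size = 0.1)
  expect_lt(max(abs(flatten_image(plane, 1)$heights)), 1e-9)

  const <- topography_image(matrix(7.5, 16, 16), pixel_size = 0.1)
  expect_lt(max(abs(flatten_image(const, 0)$heights)), 1e-12)

  quad <- topography_image(0.5 * r^2 - c_^2 + r * c_ + 4, pixel_size = 0.1)
  expect_lt(max(abs(flatten_image(quad, 2)$heights)), 1e-6)

  stair <- gen_topography(noiseless_topo(), c(32L, 96L), 0.16, seed = 1)
  f1 <- flatten_image(stair, 1)
  f2 <- flatten_image(f1, 1)
  expect_equal(f1$heights, f2$heights, tolerance = 1e-9)
  expect_lt(abs(mean(f1$heights)), 1e-9)
  expect_error(flatten_image(stair, 3), "order")
})

test_that("plane flattening preserves staircase jump magnitudes", {
  # oracle: explicit least-squares plane on a small grid, subtracted by hand
  stair_row <- rep(c(0, 430.2, 860.4), each = 8)
  z <- matrix(stair_row, 16, 24, byrow = TRUE) + outer(1:16, 1:24, function(i, j) 2 * i - j)
  img <- topography_image(z, pixel_size = 0.5)
  df <- data.frame(z = as.vector(z),
                   r = as.vector(row(z)), c_ = as.vector(col(z)))
  oracle <- matrix(resid(lm(z ~ r + c_, df)), 16, 24)
  flat <- flatten_image(img, 1)
  expect_equal(flat$heights, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  # jumps across terrace boundaries survive affine removal
  jumps <- flat$heights[1, c(9, 17)] - flat$heights[1, c(8, 16)]
  raw_jumps <- z[1, c(9, 17)] - z[1, c(8, 16)]
  expect_equal(jumps, raw_jumps - coef(lm(z ~ r + c_, df))[["c_"]],
               tolerance = 1e-9)
})

test_that("profiles carry physical positions and support band averaging", {
  img <- topography_image(matrix(rnorm(50 * 200), 50, 200), pixel_size = 0.25)
  p <- extract_profile(img, 10)
  expect_identical(length(p$positions), 200L)
  expect_equal(max(p$positions), 199 * 0.25)
  expect_identical(p$heights, img$heights[10, ])
  expect_error(extract_profile(img, 51), "out of bounds")
  expect_error(extract_profile(img, 10, band = 4), "odd")

  # averaging k rows shrinks white-noise sd by ~sqrt(k)
  sds <- replicate(40, {
    im <- topography_image(matrix(rnorm(25 * 400), 25, 400), pixel_size = 0.1)
    c(sd(extract_profile(im, 13, band = 1)$heights),
      sd(extract_profile(im, 13, band = 9)$heights))
  })
  ratio <- mean(sds[1, ]) / mean(sds[2, ])
  expect_equal(ratio, 3, tolerance = 0.15)
})

test_that("step detection recovers noiseless staircases exactly", {
  img <- gen_topography(noiseless_topo(step_height_mean = 430.2),
                        c(32L, 128L), 15 / 127, seed = 1)
  steps <- detect_steps(extract_profile(img, 16), min_height = 100,
                        min_terrace = 0.5)
  expect_identical(nrow(steps), 4L)
  expect_true(all(steps$direction == "rise"))
  expect_true(all(abs(steps$height - 430.2) < 1e-9))
})

test_that("flat noisy profiles yield no steps; distinct rises are both found", {
  set.seed(99)
  flat <- line_profile(seq(0, 15, length.out = 256), rnorm(256, 0, 5))
  expect_identical(nrow(detect_steps(flat, min_height = 50, min_terrace = 0.5)), 0L)

  # two rises of 100 and 200 nm with 5 nm noise; oracle = terrace medians
  x <- seq(0, 12, length.out = 300)
  levels <- ifelse(x < 4, 0, ifelse(x < 8, 100, 300))
  y <- levels + rnorm(300, 0, 5)
  prof <- line_profile(x, y)
  st <- detect_steps(prof, min_height = 50, min_terrace = 1)
  expect_identical(nrow(st), 2L)
  med <- c(median(y[x < 4]), median(y[x >= 4 & x < 8]), median(y[x >= 8]))
  expect_equal(st$height, abs(diff(med)), tolerance = 1e-9)
  tol <- 3 * 5 / sqrt(100)   # 3 * noise / sqrt(terrace points)
  expect_lt(abs(st$height[1] - 100), tol)
  expect_lt(abs(st$height[2] - 200), tol)
  expect_error(detect_steps(line_profile(1:5, rnorm(5)), 50, 1), ">= 8")
})

test_that("step summaries use the fiber as the experimental unit", {
  same <- step_height_summary(rep(343.3, 8), fiber = rep(1:4, each = 2),
                              group = 1)
  expect_equal(same$mean, 343.3)
  expect_identical(same$sem, 0)
  two <- step_height_summary(c(100, 200), fiber = c("a", "b"))
  expect_equal(two$mean, 150)
  expect_equal(two$sem, 50)
  expect_error(step_height_summary(c(100, 110), fiber = c(1, 1)), ">= 2")
})

test_that("Sa and Sz match their definitions, by hand and by brute force", {
  tiny <- topography_image(matrix(c(0, 2, 4, 6), 2, 2), pixel_size = 1)
  r <- roughness(tiny, flatten_order = 0)
  expect_equal(r$Sa, 2)
  expect_equal(r$Sz, 6)

  const <- roughness(topography_image(matrix(3, 8, 8), 1), flatten_order = 0)
  expect_identical(const$Sa, 0)
  expect_identical(const$Sz, 0)

  set.seed(7)
  for (i in 1:25) {
    d <- sample(4:16, 2, replace = TRUE)
    z <- matrix(rnorm(prod(d), sd = 10), d[1], d[2])
    got <- roughness(topography_image(z, 0.5), flatten_order = NA)
    want <- brute_sa_sz(z)
    expect_equal(got$Sa, want$Sa, tolerance = 1e-13)  # machine precision
    expect_identical(got$Sz, want$Sz)
  }
})

test_that("Sa of a Gaussian surface approaches the half-normal mean", {
  set.seed(21)
  z <- matrix(rnorm(300 * 300, sd = 4), 300, 300)
  r <- roughness(topography_image(z, 0.05), flatten_order = 0)
  expect_equal(r$Sa, 4 * sqrt(2 / pi), tolerance = 0.01)
})

test_that("profile-wise Sz never exceeds areal Sz", {
  set.seed(3)
  z <- matrix(rnorm(40 * 40), 40, 40)
  img <- topography_image(z, 0.2)
  expect_lte(roughness(img, 1, sz_mode = "profile")$Sz,
             roughness(img, 1, sz_mode = "areal")$Sz)
})

test_that("crops isolate terraces from steps (two-scale roughness logic)", {
  px <- 15 / 127
  img <- gen_topography(topo_truth(step_height_sd = 0, roughness_sd = 2,
                                   tilt = 0, debris_density = 0),
                        c(128L, 128L), px, seed = 5)
  full <- crop_image(img, c(0, 0), (dim(img$heights) - 1L) * px)
  expect_identical(full$heights, img$heights)

  # 3x3 um^2 on a single terrace (terraces at x in [0,3.5), [3.5,7) um ...)
  terrace <- crop_image(img, origin = c(6, 0.2), size = c(3, 3))
  expect_lt(roughness(terrace, 1)$Sz, 430.2)

  # 15x15 um^2 spans steps: noise-free staircase bound checked noiselessly
  clean <- gen_topography(noiseless_topo(), c(128L, 128L), px, seed = 5)
  expect_gte(roughness(clean, NA)$Sz, 430.2)

  expect_error(crop_image(img, c(0, 0), c(99, 3)), "bounds")
})

test_that("flattest_crop places the small window on a step-free terrace", {
  px <- 15 / 127
  img <- gen_topography(topo_truth(step_height_sd = 0, roughness_sd = 4,
                                   tilt = 0, debris_density = 0),
                        c(128L, 128L), px, seed = 9)
  small <- flattest_crop(img, 3, sweep = "x")
  expect_lt(roughness(small, 1)$Sz, 100)          # no 430 nm step inside
  # Sa of the selected window reflects surface roughness, not steps
  expect_lt(roughness(small, 1)$Sa, 3 * 4)
  expect_error(flattest_crop(img, 99), "larger")
})
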