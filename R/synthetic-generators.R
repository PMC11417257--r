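# Per-fiber synthetic measurement generators. Every generator is a pure
# function of (truth, geometry, seed): identical arguments give bit-identical
# output, and with all noise parameters at 0 the output equals the closed-form
# staircase / piecewise / Gaussian-dip model exactly.

#' Generate a synthetic cuticle topography image
#'
#' Builds a height grid as tilt plane + cuticle staircase along the column
#' (fast-scan) axis + correlated Gaussian roughness + optional debris bumps.
#' Terraces have length `terrace_length`; each rise is drawn from
#' `Normal(step_height_mean, step_height_sd^2)`. If the terrace length
#' exceeds the image width the image contains no step.
#'
#' @param truth A [topo_truth()] object.
#' @param size Integer `(rows, cols)`; both >= 16.
#' @param pixel_size Pixel size, um (> 0).
#' @param seed Integer seed.
#' @return A [topography_image()].
#' @export
#' @examples
#' img <- gen_topography(topo_truth(roughness_sd = 0, step_height_sd = 0),
#'                       size = c(32, 64), pixel_size = 0.25, seed = 1)
gen_topography <- function(truth, size, pixel_size, seed) {
  stopifnot(inherits(truth, "topo_truth"))
  size <- as.integer(size)
  if (length(size) != 2L || any(!is.finite(size)) || any(size < 16L)) {
    stop("`size` must be (rows, cols) with both >= 16", call. = FALSE)
  }
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  rows <- size[1]; cols <- size[2]
  x_um <- (seq_len(cols) - 1L) * pixel_size
  y_um <- (seq_len(rows) - 1L) * pixel_size

  # staircase: terrace index along x; cumulative rises
  ter_idx <- floor(x_um / truth$terrace_length)
  n_ter <- max(ter_idx) + 1L

  with_seed(seed, {
    rises <- if (n_ter > 1L) {
      stats::rnorm(n_ter - 1L, truth$step_height_mean, truth$step_height_sd)
    } else {
      numeric(0)
    }
    stair_levels <- c(0, cumsum(rises))
    base_row <- truth$tilt * x_um + stair_levels[ter_idx + 1L]
    z <- matrix(base_row, nrow = rows, ncol = cols, byrow = TRUE)

    if (truth$roughness_sd > 0) {
      field <- matrix(stats::rnorm(rows * cols), rows, cols)
      sigma_px <- truth$roughness_correlation_length / pixel_size
      if (sigma_px > 0.25) field <- gaussian_blur(field, sigma_px)
      field <- field - mean(field)
      field <- field * (truth$roughness_sd / stats::sd(as.vector(field)))
      z <- z + field
    }

    if (truth$debris_density > 0 && truth$debris_height > 0) {
      area <- (rows * pixel_size) * (cols * pixel_size)
      n_debris <- stats::rpois(1L, truth$debris_density * area)
      if (n_debris > 0) {
        dx <- stats::runif(n_debris, 0, max(x_um))
        dy <- stats::runif(n_debris, 0, max(y_um))
        sig <- 0.25  # debris bump lateral sigma, um
        for (i in seq_len(n_debris)) {
          gx <- exp(-(x_um - dx[i])^2 / (2 * sig^2))
          gy <- exp(-(y_um - dy[i])^2 / (2 * sig^2))
          z <- z + truth$debris_height * outer(gy, gx)
        }
      }
    }
    topography_image(z, pixel_size)
  })
}

# separable Gaussian blur with reflective padding
gaussian_blur <- function(m, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  g <- stats::dnorm(seq(-half, half), sd = sigma_px)
  g <- g / sum(g)
  blur_vec <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1L, 1L)])
    as.numeric(stats::filter(pad, g, sides = 2))[(half + 1L):(half + n)]
  }
  m <- apply(m, 2L, blur_vec)
  t(apply(m, 1L, blur_vec))
}

#' Generate a synthetic force-distance curve
#'
#' Approach branch: zero-force baseline far from the surface, an attractive
#' snap-in dip to `-attraction_depth` at the contact point, then a linear
#' repulsive rise with the series-spring contact slope up to the setpoint.
#' Retract branch: the same contact line extended down to `-adhesion_depth`
#' before pull-off back to the baseline. Gaussian force noise is added to
#' both branches. Displacement increases toward the sample; positive force
#' is repulsive.
#'
#' @param truth An [fd_truth()] object.
#' @param n_points Points per branch (>= 50).
#' @param seed Integer seed.
#' @return An [fd_curve()]; the retract branch is stored in time order
#'   (decreasing displacement).
#' @export
#' @examples
#' crv <- gen_fd_curve(fd_truth(noise_sd = 0), n_points = 200, seed = 1)
gen_fd_curve <- function(truth, n_points = 400L, seed) {
  stopifnot(inherits(truth, "fd_truth"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 50L) {
    stop("`n_points` must be >= 50", call. = FALSE)
  }
  if (truth$setpoint <= 0) stop("`setpoint` must be > 0", call. = FALSE)

  s <- fd_contact_slope(truth)
  att <- truth$attraction_depth
  adh <- truth$adhesion_depth
  contact_len <- (truth$setpoint + att) / s
  snap_w <- max(contact_len * 0.04, 1)      # snap-in ramp width, nm
  total <- 2 * contact_len + snap_w         # half the range is non-contact
  d <- seq(0, total, length.out = n_points)
  d_c <- total - contact_len                # contact point

  f_app <- ifelse(d < d_c - snap_w, 0,
                  ifelse(d < d_c, -att * (d - (d_c - snap_w)) / snap_w,
                         -att + s * (d - d_c)))
  f_app[which.min(abs(d - d_c))] <- -att    # grid hits the dip floor exactly

  d_pull <- d_c + (att - adh) / s
  f_ret <- ifelse(d >= d_pull, -att + s * (d - d_c), 0)
  j <- which.min(abs(d - d_pull))
  if (d_pull >= 0 && d_pull <= total) f_ret[j] <- -adh

  with_seed(seed, {
    if (truth$noise_sd > 0) {
      f_app <- f_app + stats::rnorm(n_points, 0, truth$noise_sd)
      f_ret <- f_ret + stats::rnorm(n_points, 0, truth$noise_sd)
    }
    fd_curve(cbind(d, f_app), cbind(rev(d), rev(f_ret)),
             spring_constant = truth$spring_constant)
  })
}

#' Generate a synthetic tensile stress-strain curve
#'
#' Stress follows the three-region piecewise-linear model of
#' [tensile_model_stress()] on an equally spaced strain grid from 0 to the
#' fracture strain, where the record ends; Gaussian stress noise is added.
#'
#' @param truth A [tensile_truth()] object.
#' @param n_points Number of samples (>= 100).
#' @param seed Integer seed.
#' @return A [tensile_curve()].
#' @export
#' @examples
#' crv <- gen_tensile_curve(tensile_truth(noise_sd = 0), n_points = 471, seed = 1)
gen_tensile_curve <- function(truth, n_points = 500L, seed) {
  stopifnot(inherits(truth, "tensile_truth"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 100L) {
    stop("`n_points` must be >= 100", call. = FALSE)
  }
  strain <- seq(0, truth$fracture_strain, length.out = n_points)
  stress <- tensile_model_stress(truth, strain)
  with_seed(seed, {
    if (truth$noise_sd > 0) {
      stress <- stress + stats::rnorm(n_points, 0, truth$noise_sd)
    }
    tensile_curve(strain, stress = stress, diameter = truth$diameter)
  })
}

#' Generate a synthetic FT-IR transmittance spectrum
#'
#' Transmittance is `100 + baseline_slope * (nu - nu_min)` minus a Gaussian
#' dip per configured band, plus Gaussian noise, clipped below at 0 %T.
#' Bands whose center falls outside the wavenumber range are skipped with a
#' warning.
#'
#' @param truth A [spectrum_truth()] object.
#' @param wavenumber_range `(min, max)` in cm^-1, min < max.
#' @param resolution Sampling interval, cm^-1 (> 0).
#' @param seed Integer seed.
#' @return An [ftir_spectrum()].
#' @export
#' @examples
#' sp <- gen_spectrum(spectrum_truth(keratin_bands("control"), noise_sd = 0),
#'                    seed = 1)
gen_spectrum <- function(truth, wavenumber_range = c(400, 4000),
                         resolution = 4, seed) {
  stopifnot(inherits(truth, "spectrum_truth"))
  if (length(wavenumber_range) != 2L ||
      !(wavenumber_range[1] < wavenumber_range[2])) {
    stop("`wavenumber_range` must be (min, max) with min < max", call. = FALSE)
  }
  check_scalar(resolution, "resolution", lower = 0, strict_lower = TRUE)
  nu <- seq(wavenumber_range[1], wavenumber_range[2], by = resolution)
  tr <- 100 + truth$baseline_slope * (nu - nu[1])
  for (i in seq_len(nrow(truth$bands))) {
    b <- truth$bands[i, ]
    if (b$center < wavenumber_range[1] || b$center > wavenumber_range[2]) {
      warning(sprintf("band '%s' center %.1f cm^-1 outside range; skipped",
                      b$name, b$center), call. = FALSE)
      next
    }
    tr <- tr - b$depth * exp(-(nu - b$center)^2 / (2 * b$width^2))
  }
  with_seed(seed, {
    if (truth$noise_sd > 0) tr <- tr + stats::rnorm(length(nu), 0, truth$noise_sd)
    ftir_spectrum(nu, pmin(pmax(tr, 0), 110))
  })
}
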