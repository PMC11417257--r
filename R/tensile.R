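# Tensile stress-strain analysis: engineering-stress conversion, three-region
# (pre-yield / yield / post-yield) segmentation by continuous piecewise-linear
# least squares, and feature extraction.

GF_TO_MN <- 9.80665  # 1 gram-force in mN

#' Convert force to engineering stress
#'
#' `sigma = F / A` with a circular cross-section `A = pi (d/2)^2`. Forces in
#' mN and diameters in um give stress in MPa. An optional instrument gauge
#' pre-tension in gram-force (1 gf = 9.80665 mN) is subtracted from the
#' force before conversion.
#'
#' @param force_mN Force values, mN (>= 0).
#' @param diameter Fiber diameter, um (> 0).
#' @param gauge_force_gf Optional pre-tension, gram-force, subtracted first.
#' @param clamp Clamp negative post-subtraction forces to 0 (default FALSE).
#' @return Stress values, MPa.
#' @export
#' @examples
#' compute_stress(100, diameter = 80)  # ~19.89 MPa
compute_stress <- function(force_mN, diameter, gauge_force_gf = NULL,
                           clamp = FALSE) {
  check_scalar(diameter, "diameter", lower = 0, strict_lower = TRUE)
  force_mN <- as.numeric(force_mN)
  if (any(!is.finite(force_mN))) stop("forces must be finite", call. = FALSE)
  if (!is.null(gauge_force_gf)) {
    check_scalar(gauge_force_gf, "gauge_force_gf", lower = 0)
    force_mN <- force_mN - gauge_force_gf * GF_TO_MN
  }
  if (clamp) force_mN <- pmax(force_mN, 0)
  area_um2 <- pi * (diameter / 2)^2
  # F[mN] * 1e-3 [N] / (A[um^2] * 1e-12 [m^2]) = F/A * 1e9 Pa = F/A * 1e3 MPa
  force_mN / area_um2 * 1e3
}

# continuous two-knot piecewise-linear least squares at fixed breakpoints
# basis: 1, x, (x-b1)+, (x-b2)+
pw3_fit <- function(x, y, b1, b2) {
  X <- cbind(1, x, pmax(x - b1, 0), pmax(x - b2, 0))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  slopes <- c(beta[2], beta[2] + beta[3], beta[2] + beta[3] + beta[4])
  list(sse = sum(fit$residuals^2), slopes = unname(slopes),
       coef = unname(beta))
}

#' Segment a tensile curve into pre-yield, yield and post-yield regions
#'
#' Fits a continuous three-piece linear model (free slopes, shared
#' breakpoints) by exhaustive search over a coarse breakpoint grid followed
#' by local refinement down to the strain grid spacing; deterministic, with
#' no random initialization. The middle (yield plateau) slope must be the
#' smallest of the three; otherwise, or when a single line already explains
#' the curve, the result is flagged degenerate and the whole record treated
#' as pre-yield.
#'
#' @param curve A [tensile_curve()] spanning strain >= 0.1 with >= 100 points.
#' @param n_grid Coarse grid size per breakpoint (default 30).
#' @return List with `yield_bounds` (two strains), `slopes` (three slopes,
#'   MPa), `sse`, `degenerate` (flag) and `r_squared` of the piecewise fit.
#' @export
#' @examples
#' crv <- gen_tensile_curve(tensile_truth(noise_sd = 0), n_points = 471, seed = 1)
#' segment_regions(crv)$yield_bounds
segment_regions <- function(curve, n_grid = 30L) {
  stopifnot(inherits(curve, "tensile_curve"))
  x <- curve$strain; y <- curve$stress
  n <- length(x)
  if (n < 100L) stop("curve must have >= 100 points", call. = FALSE)
  if (max(x) < 0.1) stop("curve must span strain >= 0.1", call. = FALSE)

  span <- max(x) - min(x)
  margin <- 0.03 * span
  lo <- min(x) + margin; hi <- max(x) - margin
  grid <- seq(lo, hi, length.out = n_grid)

  best <- NULL
  for (i in seq_len(n_grid - 1L)) {
    for (j in (i + 1L):n_grid) {
      fit <- pw3_fit(x, y, grid[i], grid[j])
      if (is.null(best) || fit$sse < best$sse) {
        best <- c(fit, list(b = c(grid[i], grid[j])))
      }
    }
  }
  # coordinate-descent refinement down to the strain grid spacing
  px <- span / (n - 1L)
  width <- diff(grid[1:2])
  while (width > px / 2) {
    width <- width / 4
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in 1:2) {
        cand <- best$b[k] + seq(-2, 2) * width
        cand <- cand[cand > lo - 1e-12 & cand < hi + 1e-12]
        for (b in cand) {
          bb <- best$b; bb[k] <- b
          if (bb[1] >= bb[2]) next
          fit <- pw3_fit(x, y, bb[1], bb[2])
          if (fit$sse < best$sse - 1e-12 * max(best$sse, 1)) {
            best <- c(fit, list(b = bb))
            improved <- TRUE
          }
        }
      }
    }
  }

  # snap breakpoints to the nearest sample strain
  b <- vapply(best$b, function(v) x[which.min(abs(x - v))], 0)
  fit <- pw3_fit(x, y, b[1], b[2])
  if (fit$sse <= best$sse * (1 + 1e-9)) best <- c(fit, list(b = b))

  one_line <- ls_line(x, y)
  sse1 <- sum((y - one_line["intercept"] - one_line["slope"] * x)^2)
  slopes <- best$slopes
  degenerate <- FALSE
  if (sse1 <= max(best$sse * (1 + 1e-9), 1e-12 * sum(y^2))) {
    degenerate <- TRUE  # a single line already explains the record
  } else {
    fstat <- ((sse1 - best$sse) / 4) / (best$sse / max(n - 6L, 1L))
    if (!is.finite(fstat) || stats::pf(fstat, 4, n - 6L, lower.tail = FALSE) > 1e-3) {
      degenerate <- TRUE
    }
  }
  if (!degenerate && which.min(abs(slopes)) != 2L) degenerate <- TRUE

  list(yield_bounds = if (degenerate) c(NA_real_, NA_real_) else best$b,
       slopes = slopes, sse = best$sse, degenerate = degenerate,
       r_squared = r_squared(y, y - resid_pw3(x, y, best)))
}

resid_pw3 <- function(x, y, best) {
  X <- cbind(1, x, pmax(x - best$b[1], 0), pmax(x - best$b[2], 0))
  y - as.vector(X %*% best$coef)
}

#' Extract tensile features from a stress-strain curve
#'
#' Runs [segment_regions()], then reports: the elastic modulus as the
#' least-squares slope over the pre-yield segment, the yield stress as the
#' highest stress within the pre-yield segment, and the fracture stress and
#' strain as the last recorded sample (the instrument stops at break). An
#' optional detector flags a large terminal stress drop in real traces
#' (`drop_detect = TRUE`); it is off by default because synthetic records
#' end exactly at fracture.
#'
#' @param curve A [tensile_curve()].
#' @param drop_detect Truncate the record at the largest terminal stress
#'   drop (> 50 % of the running maximum) before analysis.
#' @return A one-row data frame with `elastic_modulus`, `yield_stress`,
#'   `yield_strain_low`, `yield_strain_high`, `fracture_stress`,
#'   `fracture_strain`, `r_squared`, `degenerate`.
#' @export
#' @examples
#' crv <- gen_tensile_curve(tensile_truth(noise_sd = 0), n_points = 471, seed = 1)
#' tensile_features(crv)
tensile_features <- function(curve, drop_detect = FALSE) {
  stopifnot(inherits(curve, "tensile_curve"))
  if (drop_detect) {
    run_max <- cummax(curve$stress)
    drop <- which(run_max - curve$stress > 0.5 * run_max & run_max > 0)
    if (length(drop)) {
      keep <- seq_len(drop[1] - 1L)
      curve <- tensile_curve(curve$strain[keep], stress = curve$stress[keep],
                             diameter = curve$diameter, id = curve$id)
    }
  }
  seg <- segment_regions(curve)
  x <- curve$strain; y <- curve$stress
  pre_hi <- if (seg$degenerate) max(x) else seg$yield_bounds[1]
  pre <- x <= pre_hi + 1e-12
  line <- ls_line(x[pre], y[pre])
  fitted <- line["intercept"] + line["slope"] * x[pre]
  data.frame(elastic_modulus = unname(line["slope"]),
             yield_stress = max(y[pre]),
             yield_strain_low = seg$yield_bounds[1],
             yield_strain_high = seg$yield_bounds[2],
             fracture_stress = y[length(y)],
             fracture_strain = x[length(x)],
             r_squared = r_squared(y[pre], fitted),
             degenerate = seg$degenerate)
}
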