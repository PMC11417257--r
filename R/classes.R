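# S3 containers for the four measurement modalities.

#' Topography image
#'
#' A rectangular height grid with a physical pixel size. Coordinates are
#' row-major with the origin at the top-left pixel (0-based indices);
#' physical positions refer to pixel centers, so pixel `(i, j)` sits at
#' `(i, j) * pixel_size` um.
#'
#' @param heights Numeric matrix of heights, nm. All values must be finite.
#' @param pixel_size Physical pixel size, um per pixel (square pixels).
#' @param id Source identifier.
#' @return An object of class `topography_image`.
#' @export
#' @examples
#' img <- topography_image(matrix(0, 32, 32), pixel_size = 0.1)
topography_image <- function(heights, pixel_size, id = "") {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    stop("`heights` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(heights))) stop("all heights must be finite", call. = FALSE)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(heights = heights, pixel_size = pixel_size, id = as.character(id)),
            class = "topography_image")
}

#' @export
print.topography_image <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf("<topography_image> %d x %d px, %.4g um/px (%.3g x %.3g um)\n",
              d[1], d[2], x$pixel_size,
              (d[1] - 1) * x$pixel_size, (d[2] - 1) * x$pixel_size))
  cat(sprintf("  height range: %.2f .. %.2f nm%s\n",
              min(x$heights), max(x$heights),
              if (nzchar(x$id)) paste0("  id: ", x$id) else ""))
  invisible(x)
}

#' Line profile extracted from a topography image
#'
#' @param positions Strictly increasing positions, um.
#' @param heights Heights, nm; same length as `positions`.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, heights) {
  if (length(positions) != length(heights)) {
    stop("`positions` and `heights` must have equal length", call. = FALSE)
  }
  if (length(positions) && any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  structure(list(positions = as.numeric(positions), heights = as.numeric(heights)),
            class = "line_profile")
}

#' Force-distance curve
#'
#' Cantilever force versus piezo displacement for the approach and retract
#' branches of one indentation. Repo-wide convention: displacement is in nm
#' and increases toward the sample; positive force is repulsive, attractive
#' forces are negative.
#'
#' @param approach Two-column matrix or data frame (displacement_nm, force_nN)
#'   with strictly increasing displacement.
#' @param retract Same layout; displacement strictly monotone (stored in
#'   time order, i.e. decreasing displacement).
#' @param spring_constant Cantilever force constant, nN/nm.
#' @param id Source identifier.
#' @return An object of class `fd_curve`.
#' @export
fd_curve <- function(approach, retract, spring_constant, id = "") {
  branch <- function(b, name) {
    b <- as.matrix(b)
    if (ncol(b) != 2L) stop(sprintf("`%s` must have two columns", name), call. = FALSE)
    if (nrow(b) < 20L) stop(sprintf("`%s` must have >= 20 points", name), call. = FALSE)
    d <- diff(b[, 1])
    if (!(all(d > 0) || all(d < 0))) {
      stop(sprintf("`%s` displacement must be strictly monotone", name), call. = FALSE)
    }
    colnames(b) <- c("displacement_nm", "force_nN")
    b
  }
  check_scalar(spring_constant, "spring_constant", lower = 0, strict_lower = TRUE)
  structure(list(approach = branch(approach, "approach"),
                 retract = branch(retract, "retract"),
                 spring_constant = spring_constant, id = as.character(id)),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("<fd_curve> %d approach / %d retract points, k = %.3g nN/nm%s\n",
              nrow(x$approach), nrow(x$retract), x$spring_constant,
              if (nzchar(x$id)) paste0("  id: ", x$id) else ""))
  invisible(x)
}

#' Tensile stress-strain curve
#'
#' Strain is stored as a fraction (0.47 = 47 %); stress in MPa computed from
#' force via sigma = F / A with a circular cross-section A = pi (d/2)^2.
#'
#' @param strain Non-decreasing strain fractions starting at 0.
#' @param stress Stress, MPa. Exactly one of `stress` / `force_mN` required.
#' @param force_mN Force, mN; converted via [compute_stress()].
#' @param diameter Fiber diameter, um.
#' @param gauge_force_gf Optional instrument pre-tension in gram-force; when
#'   supplied together with `force_mN` and `subtract_gauge = TRUE` it is
#'   subtracted before the stress conversion.
#' @param subtract_gauge Subtract the gauge pre-tension? Default `FALSE`.
#' @param id Source identifier.
#' @return An object of class `tensile_curve`.
#' @export
tensile_curve <- function(strain, stress = NULL, force_mN = NULL, diameter,
                          gauge_force_gf = NULL, subtract_gauge = FALSE,
                          id = "") {
  strain <- as.numeric(strain)
  if (length(strain) && any(diff(strain) < 0)) {
    stop("`strain` must be non-decreasing", call. = FALSE)
  }
  check_scalar(diameter, "diameter", lower = 0, strict_lower = TRUE)
  if (is.null(stress) == is.null(force_mN)) {
    stop("supply exactly one of `stress` or `force_mN`", call. = FALSE)
  }
  if (is.null(stress)) {
    stress <- compute_stress(force_mN, diameter,
                             gauge_force_gf = if (subtract_gauge) gauge_force_gf,
                             clamp = TRUE)
  }
  stress <- as.numeric(stress)
  if (length(stress) != length(strain)) {
    stop("`strain` and stress/force must have equal length", call. = FALSE)
  }
  if (any(!is.finite(stress))) stop("stress must be finite", call. = FALSE)
  structure(list(strain = strain, stress = stress, diameter = diameter,
                 gauge_force_gf = gauge_force_gf, id = as.character(id)),
            class = "tensile_curve")
}

#' @export
print.tensile_curve <- function(x, ...) {
  cat(sprintf("<tensile_curve> %d points, strain 0 .. %.3g, d = %.3g um%s\n",
              length(x$strain), max(x$strain), x$diameter,
              if (nzchar(x$id)) paste0("  id: ", x$id) else ""))
  invisible(x)
}

#' FT-IR transmittance spectrum
#'
#' @param wavenumbers Strictly increasing wavenumbers, cm^-1, within the
#'   instrument span 400-4000 cm^-1.
#' @param transmittance Transmittance, %T, in \[0, 110\].
#' @param id Source identifier.
#' @return An object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumbers, transmittance, id = "") {
  wavenumbers <- as.numeric(wavenumbers)
  transmittance <- as.numeric(transmittance)
  if (length(wavenumbers) != length(transmittance)) {
    stop("`wavenumbers` and `transmittance` must have equal length", call. = FALSE)
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("`wavenumbers` must be strictly increasing", call. = FALSE)
  }
  if (min(wavenumbers) < 400 - 1e-9 || max(wavenumbers) > 4000 + 1e-9) {
    stop("wavenumbers must lie within the instrument span 400-4000 cm^-1",
         call. = FALSE)
  }
  if (any(transmittance < 0 | transmittance > 110)) {
    stop("transmittance must lie in [0, 110] %T", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, transmittance = transmittance,
                 id = as.character(id)),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %d points, %.0f-%.0f cm^-1%s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              if (nzchar(x$id)) paste0("  id: ", x$id) else ""))
  invisible(x)
}
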