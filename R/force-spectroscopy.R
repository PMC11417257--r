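# Force-distance curve analysis: baseline correction, snap-in (attraction),
# pull-off (adhesion) and contact-stiffness extraction.
#
# Conventions (repo-wide): displacement in nm increases toward the sample;
# positive force is repulsive; attraction and adhesion are reported as
# magnitudes of the negative (attractive) excursions.
#
# Detection threshold: dips count as "detected" when they pass 4x the
# baseline noise. The statistic is a minimum over a whole branch (hundreds
# of samples), so a 3-sigma rule would flag pure noise in a third of
# dip-free branches; at 4 sigma the false-detection rate is ~1 % per branch.

# far-from-surface segment of the approach branch: the fraction of points at
# the smallest displacement
far_segment <- function(curve, fraction = 0.25) {
  app <- curve$approach
  n <- nrow(app)
  n_far <- max(5L, floor(n * fraction))
  app[order(app[, 1])[seq_len(n_far)], , drop = FALSE]
}

#' Baseline-correct a force-distance curve
#'
#' Fits a straight line to the far-from-surface (non-contact) segment of the
#' approach branch and subtracts it from both branches, so that the
#' non-contact force is zero on average and constant offsets or a linear
#' baseline tilt do not affect any downstream feature. Fails when the far
#' segment is not force-flat (all points in contact).
#'
#' @param curve An [fd_curve()].
#' @param fraction Fraction of approach points (smallest displacement)
#'   treated as non-contact; default 0.25.
#' @return The corrected [fd_curve()], with attributes `baseline` (intercept,
#'   slope) and `noise_sd` (robust far-segment noise estimate).
#' @export
baseline_correct <- function(curve, fraction = 0.25) {
  stopifnot(inherits(curve, "fd_curve"))
  check_scalar(fraction, "fraction", lower = 0.05, upper = 0.9)
  far <- far_segment(curve, fraction)
  line <- ls_line(far[, 1], far[, 2])
  # a non-contact segment must be flat relative to the cantilever constant
  if (abs(line["slope"]) > 0.25 * curve$spring_constant) {
    stop("cannot identify a non-contact region (approach appears fully in contact)",
         call. = FALSE)
  }
  correct <- function(b) {
    b[, 2] <- b[, 2] - (line["intercept"] + line["slope"] * b[, 1])
    b
  }
  out <- curve
  out$approach <- correct(curve$approach)
  out$retract <- correct(curve$retract)
  resid <- out$approach[order(out$approach[, 1])[seq_len(nrow(far))], 2]
  attr(out, "baseline") <- unname(line)
  attr(out, "noise_sd") <- stats::mad(resid)
  out
}

fd_noise_sd <- function(curve) {
  ns <- attr(curve, "noise_sd")
  if (is.null(ns)) ns <- stats::mad(far_segment(curve)[, 2])
  ns
}

#' Attraction force from the approach branch (snap-in)
#'
#' The attraction force is the magnitude of the deepest attractive (negative)
#' excursion of the baselined approach branch, reached at the snap-in dip
#' just before contact. Reports 0 with `detected = FALSE` when no excursion
#' falls below 4x the baseline noise (the minimum is taken over the whole
#' branch, so a 3-sigma rule would fire on noise alone).
#'
#' @param curve A baselined [fd_curve()] (see [baseline_correct()]).
#' @return List with `attraction` (nN, >= 0), `detected` (logical) and
#'   `position` (displacement of the minimum, nm).
#' @export
detect_snap_in <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  f <- curve$approach[, 2]
  i <- which.min(f)
  noise <- fd_noise_sd(curve)
  detected <- f[i] < -4 * noise
  list(attraction = if (detected) -f[i] else 0, detected = detected,
       position = curve$approach[i, 1])
}

#' Adhesion force from the retract branch (pull-off)
#'
#' The adhesion force is the magnitude of the deepest attractive excursion of
#' the baselined retract branch, reached just before pull-off. Reports 0
#' with `detected = FALSE` when no excursion falls below 4x the baseline
#' noise.
#'
#' @param curve A baselined [fd_curve()].
#' @return List with `adhesion` (nN, >= 0), `detected` and `position` (nm).
#' @export
detect_pull_off <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  f <- curve$retract[, 2]
  i <- which.min(f)
  noise <- fd_noise_sd(curve)
  detected <- f[i] < -4 * noise
  list(adhesion = if (detected) -f[i] else 0, detected = detected,
       position = curve$retract[i, 1])
}

#' Contact stiffness from the approach branch
#'
#' The contact point is the first displacement after the snap-in minimum at
#' which the force crosses +3x the baseline noise. The stiffness is the
#' least-squares slope of force versus piezo displacement over the upper
#' `fit_fraction` of the contact region (raw slope, not corrected for
#' cantilever compliance; it is therefore bounded above by the cantilever
#' spring constant in series with the sample). The compliance-corrected
#' sample stiffness `k * s / (k - s)` is returned alongside.
#'
#' @param curve A baselined [fd_curve()].
#' @param fit_fraction Upper fraction of the contact region used in the fit
#'   (default 0.7).
#' @return List with `stiffness` (nN/nm), `contact_point` (nm), `r_squared`,
#'   `sample_stiffness` (series-spring inversion, `Inf` when the raw slope
#'   reaches the cantilever constant) and `low_quality` (TRUE when
#'   R^2 < 0.9).
#' @export
fit_stiffness <- function(curve, fit_fraction = 0.7) {
  stopifnot(inherits(curve, "fd_curve"))
  check_scalar(fit_fraction, "fit_fraction", lower = 0.05, upper = 1)
  app <- curve$approach
  o <- order(app[, 1])
  d <- app[o, 1]; f <- app[o, 2]
  noise <- fd_noise_sd(curve)
  i_min <- which.min(f)
  thr <- max(3 * noise, 1e-12)
  after <- which(f > thr & seq_along(f) > i_min)
  if (!length(after)) stop("no contact region found above the noise threshold",
                           call. = FALSE)
  i_c <- after[1]
  contact_d <- d[i_c:length(d)]
  contact_f <- f[i_c:length(f)]
  if (length(contact_d) < 10L) stop("contact region too short (< 10 points)",
                                    call. = FALSE)
  # upper fit_fraction of the contact region by displacement
  cut <- contact_d[1] + (1 - fit_fraction) * (contact_d[length(contact_d)] -
                                                contact_d[1])
  sel <- contact_d >= cut
  if (sum(sel) < 10L) sel <- rep(TRUE, length(contact_d))
  line <- ls_line(contact_d[sel], contact_f[sel])
  fitted <- line["intercept"] + line["slope"] * contact_d[sel]
  r2 <- r_squared(contact_f[sel], fitted)
  s <- unname(line["slope"])
  if (s <= 0) stop("non-positive contact slope; invalid contact region",
                   call. = FALSE)
  k <- curve$spring_constant
  list(stiffness = s,
       contact_point = d[i_c],
       r_squared = r2,
       sample_stiffness = if (s < k) k * s / (k - s) else Inf,
       low_quality = r2 < 0.9)
}

#' Extract all force-distance features from a curve
#'
#' Baseline-corrects the curve, then composes [detect_snap_in()] (approach
#' only), [detect_pull_off()] (retract only) and [fit_stiffness()]. Constant
#' force offsets are absorbed by the baseline correction and change no
#' feature.
#'
#' @param curve An [fd_curve()].
#' @param fit_fraction Passed to [fit_stiffness()].
#' @param baseline_fraction Passed to [baseline_correct()].
#' @return A one-row data frame with columns `stiffness`, `adhesion`,
#'   `attraction`, `contact_point`, `r_squared`, `sample_stiffness`,
#'   `attraction_detected`, `adhesion_detected`, `low_quality`.
#' @export
#' @examples
#' crv <- gen_fd_curve(fd_truth(), n_points = 300, seed = 7)
#' fd_features(crv)
fd_features <- function(curve, fit_fraction = 0.7, baseline_fraction = 0.25) {
  stopifnot(inherits(curve, "fd_curve"))
  bc <- tryCatch(baseline_correct(curve, baseline_fraction),
                 error = function(e) {
                   stop(sprintf("curve '%s': %s", curve$id, conditionMessage(e)),
                        call. = FALSE)
                 })
  snap <- detect_snap_in(bc)
  pull <- detect_pull_off(bc)
  stiff <- tryCatch(fit_stiffness(bc, fit_fraction),
                    error = function(e) {
                      stop(sprintf("curve '%s': %s", curve$id,
                                   conditionMessage(e)), call. = FALSE)
                    })
  data.frame(stiffness = stiff$stiffness, adhesion = pull$adhesion,
             attraction = snap$attraction, contact_point = stiff$contact_point,
             r_squared = stiff$r_squared,
             sample_stiffness = stiff$sample_stiffness,
             attraction_detected = snap$detected,
             adhesion_detected = pull$detected,
             low_quality = stiff$low_quality)
}
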