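# FT-IR band quantification in transmittance (%T). Band "intensity" is
# measured as the dip depth below a local linear baseline drawn through the
# window endpoints; a deeper dip means stronger absorption. No absorbance
# (-log T) or ATR penetration-depth correction is applied: the analysis
# operates on %T as acquired.

#' Default keratin band table
#'
#' Eight quantification windows (cm^-1): amide I 1600-1690, amide II
#' 1480-1575, amide III 1229-1301, amide B 3030-3100, lipid 3110-3160, water
#' 3180-3370 (broad), cysteic acid 1020-1060 (narrow window around
#' 1035.9 cm^-1) and the dye-induced NH2 scissoring band 1560-1590 (around
#' 1575 cm^-1, absent in undyed hair). Windows may overlap.
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
default_bands <- function() {
  data.frame(
    name = c("amide_I", "amide_II", "amide_III", "amide_B",
             "lipid", "water", "cysteic_acid", "nh2"),
    low  = c(1600, 1480, 1229, 3030, 3110, 3180, 1020, 1560),
    high = c(1690, 1575, 1301, 3100, 3160, 3370, 1060, 1590),
    stringsAsFactors = FALSE)
}

spectrum_window <- function(spectrum, window) {
  if (length(window) != 2L || !(window[1] < window[2])) {
    stop("`window` must be (low, high) with low < high", call. = FALSE)
  }
  if (window[1] < min(spectrum$wavenumbers) - 1e-9 ||
      window[2] > max(spectrum$wavenumbers) + 1e-9) {
    stop("window lies outside the spectrum range", call. = FALSE)
  }
  which(spectrum$wavenumbers >= window[1] - 1e-9 &
          spectrum$wavenumbers <= window[2] + 1e-9)
}

ftir_noise_sd <- function(spectrum) diff_noise_sd(spectrum$transmittance)

ma3 <- function(y) {
  n <- length(y)
  if (n < 3L) return(y)
  c(y[1], (y[-c(1, 2)] + y[-c(1, n)] + y[-c(n - 1, n)]) / 3, y[n])
}

#' Local linear baseline over a band window
#'
#' A straight line through the transmittance at the two window endpoints
#' (by default after width-3 moving-average smoothing of the whole spectrum,
#' so an endpoint anchor averages its immediate neighborhood, including
#' samples just outside the window); it is the zero-depth reference for
#' [quantify_band()]. A linear background slope moves the baseline with it
#' and leaves depths unchanged.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param window `(low, high)` in cm^-1; must contain >= 3 samples.
#' @param smooth Apply width-3 moving-average smoothing first (default TRUE).
#' @return Data frame with `wavenumber` and `baseline` (%T) over the window.
#' @export
local_baseline <- function(spectrum, window, smooth = TRUE) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  idx <- spectrum_window(spectrum, window)
  if (length(idx) < 3L) stop("window narrower than 3 samples", call. = FALSE)
  tr <- if (smooth) ma3(spectrum$transmittance) else spectrum$transmittance
  nu <- spectrum$wavenumbers[idx]
  t0 <- tr[idx[1]]; t1 <- tr[idx[length(idx)]]
  b <- t0 + (t1 - t0) * (nu - nu[1]) / (nu[length(nu)] - nu[1])
  data.frame(wavenumber = nu, baseline = b)
}

#' Quantify one band in a transmittance spectrum
#'
#' Depth is `baseline - transmittance` (%T below the local linear baseline);
#' the band center is the wavenumber of maximum depth within the window. The
#' band is reported present when its depth reaches `min_depth`, which
#' defaults to 3x a robust noise estimate of the raw spectrum. Light
#' moving-average smoothing is applied before peak picking by default: the
#' depth is a maximum over the window samples, and without smoothing its
#' extreme-value inflation makes a 3-sigma presence rule fire on noise alone
#' in a few percent of empty windows.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param name Band name.
#' @param window `(low, high)` in cm^-1.
#' @param min_depth Presence threshold, %T; `NULL` for the default.
#' @param smooth Apply light smoothing before peak picking (default TRUE).
#' @return One-row data frame with `name`, `center`, `depth`, `present`,
#'   `low`, `high`.
#' @export
#' @examples
#' sp <- gen_spectrum(spectrum_truth(keratin_bands("control"), noise_sd = 0),
#'                    seed = 1)
#' quantify_band(sp, "amide_I", c(1600, 1690))
quantify_band <- function(spectrum, name, window, min_depth = NULL,
                          smooth = TRUE) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (is.null(min_depth)) min_depth <- 3 * ftir_noise_sd(spectrum)
  check_scalar(min_depth, "min_depth", lower = 0)
  idx <- spectrum_window(spectrum, window)
  if (length(idx) < 3L) stop("window narrower than 3 samples", call. = FALSE)
  bl <- local_baseline(spectrum, window, smooth = smooth)
  tr <- if (smooth) ma3(spectrum$transmittance) else spectrum$transmittance
  depth_vec <- bl$baseline - tr[idx]
  i <- which.max(depth_vec)
  depth <- max(depth_vec[i], 0)
  present <- depth > 0 && depth >= min_depth
  data.frame(name = name, center = bl$wavenumber[i], depth = depth,
             present = present, low = window[1], high = window[2],
             stringsAsFactors = FALSE)
}

#' Quantify a table of bands
#'
#' One [quantify_band()] result per row of `bands`, in stable (input) order.
#' Overlapping windows are allowed; duplicate band names are an error.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param bands Data frame with columns `name`, `low`, `high`
#'   (default [default_bands()]).
#' @param min_depth,smooth Passed to [quantify_band()].
#' @return Data frame with one row per band.
#' @export
#' @examples
#' sp <- gen_spectrum(spectrum_truth(keratin_bands("dyed")), seed = 1)
#' quantify_bands(sp)
quantify_bands <- function(spectrum, bands = default_bands(), min_depth = NULL,
                           smooth = TRUE) {
  if (!is.data.frame(bands) || !nrow(bands) ||
      !all(c("name", "low", "high") %in% names(bands))) {
    stop("`bands` must be a non-empty data frame with name/low/high columns",
         call. = FALSE)
  }
  if (anyDuplicated(bands$name)) stop("duplicate band names", call. = FALSE)
  if (is.null(min_depth)) min_depth <- 3 * ftir_noise_sd(spectrum)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    quantify_band(spectrum, bands$name[i], c(bands$low[i], bands$high[i]),
                  min_depth = min_depth, smooth = smooth)
  })
  do.call(rbind, out)
}

#' Dose-response trend table for band depths
#'
#' Per band: mean depth with SEM per dye-cycle group, percent change versus
#' the control (dye count 0) group, and a pooled Student's t-test against
#' control with significance stars.
#'
#' @param depths Data frame with columns `fiber_id`, `dye_count`, `band`,
#'   `depth` (one row per fiber and band).
#' @return Data frame with one row per band and group.
#' @export
band_trend <- function(depths) {
  need <- c("fiber_id", "dye_count", "band", "depth")
  if (!is.data.frame(depths) || !all(need %in% names(depths))) {
    stop("`depths` needs columns fiber_id, dye_count, band, depth",
         call. = FALSE)
  }
  if (length(unique(depths$dye_count)) < 2L) {
    stop("need >= 2 dye-cycle groups", call. = FALSE)
  }
  if (!0 %in% depths$dye_count) stop("control group (dye count 0) missing",
                                     call. = FALSE)
  out <- list()
  for (b in unique(depths$band)) {
    db <- depths[depths$band == b, ]
    ctrl <- db$depth[db$dye_count == 0]
    for (g in sort(unique(db$dye_count))) {
      v <- db$depth[db$dye_count == g]
      gs <- group_summary(v, group = g)
      if (g == 0) {
        cmp <- list(t = 0, p = 1, stars = "ns")
        pc <- 0
      } else {
        cmp <- pooled_t_test(ctrl, v)
        pc <- if (mean(ctrl) != 0) percent_change(mean(ctrl), mean(v)) else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        band = b, dye_count = g, n = gs$n, mean_depth = gs$mean, sem = gs$sem,
        pct_change = pc, t = cmp$t, p = cmp$p, stars = cmp$stars,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
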