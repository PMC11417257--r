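# AFM topography metrology: polynomial flattening, line-profile extraction,
# cuticle step detection by change-point segmentation, and areal roughness
# (Sa, Sz).

#' Flatten a topography image by polynomial surface subtraction
#'
#' Subtracts the least-squares polynomial surface of total degree `order`
#' (0 = mean level, 1 = mean plane, 2 = quadratic) and returns the residual,
#' whose mean is zero. Flattening is idempotent: flattening a flattened image
#' again changes nothing beyond machine precision.
#'
#' @param image A [topography_image()].
#' @param order Polynomial order, one of 0, 1, 2.
#' @return A flattened [topography_image()].
#' @export
#' @examples
#' img <- topography_image(outer(1:32, 1:32, "+") * 1.0, pixel_size = 0.1)
#' flat <- flatten_image(img, order = 1)
flatten_image <- function(image, order = 1L) {
  stopifnot(inherits(image, "topography_image"))
  if (!order %in% c(0L, 1L, 2L)) {
    stop("`order` must be 0, 1 or 2", call. = FALSE)
  }
  z <- image$heights
  d <- dim(z)
  # centered/scaled coordinates keep the normal equations well conditioned
  r <- (seq_len(d[1]) - (d[1] + 1) / 2) / d[1]
  c_ <- (seq_len(d[2]) - (d[2] + 1) / 2) / d[2]
  R <- matrix(r, d[1], d[2])
  C <- matrix(c_, d[1], d[2], byrow = TRUE)
  X <- switch(as.character(order),
              "0" = matrix(1, length(z), 1L),
              "1" = cbind(1, as.vector(R), as.vector(C)),
              "2" = cbind(1, as.vector(R), as.vector(C), as.vector(R)^2,
                          as.vector(C)^2, as.vector(R * C)))
  fit <- stats::lm.fit(X, as.vector(z))
  out <- image
  out$heights <- matrix(fit$residuals, d[1], d[2])
  out
}

#' Extract a line profile from a topography image
#'
#' Takes one image row (optionally the average of a band of `band` adjacent
#' rows centered on it, which reduces white-noise sd by about `sqrt(band)`)
#' and converts pixel indices to physical positions via the pixel size.
#' Rows run along the fast-scan axis, perpendicular to the cuticle scale
#' edges, so a row profile crosses the cuticle staircase.
#'
#' @param image A [topography_image()].
#' @param row Row index (1-based).
#' @param band Odd number of adjacent rows to average (default 1).
#' @return A [line_profile()].
#' @export
extract_profile <- function(image, row, band = 1L) {
  stopifnot(inherits(image, "topography_image"))
  d <- dim(image$heights)
  row <- as.integer(row); band <- as.integer(band)
  if (is.na(row) || row < 1L || row > d[1]) {
    stop("`row` out of bounds", call. = FALSE)
  }
  if (is.na(band) || band < 1L || band %% 2L == 0L) {
    stop("`band` must be a positive odd integer", call. = FALSE)
  }
  half <- band %/% 2L
  lo <- row - half; hi <- row + half
  if (lo < 1L || hi > d[1]) stop("averaging band exceeds image rows", call. = FALSE)
  h <- colMeans(image$heights[lo:hi, , drop = FALSE])
  line_profile((seq_len(d[2]) - 1L) * image$pixel_size, h)
}

# ---- change-point segmentation ---------------------------------------------

# best single split of y[lo:hi] by within-segment SSE; returns (gain, index of
# last point of the left segment)
best_split <- function(y, lo, hi, min_len) {
  n <- hi - lo + 1L
  if (n < 2L * min_len) return(NULL)
  yy <- y[lo:hi]
  cs <- cumsum(yy); cs2 <- cumsum(yy^2)
  total <- cs2[n] - cs[n]^2 / n
  ks <- min_len:(n - min_len)
  sse_l <- cs2[ks] - cs[ks]^2 / ks
  nr <- n - ks
  sse_r <- (cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / nr
  gains <- total - (sse_l + sse_r)
  k <- ks[which.max(gains)]
  list(gain = max(gains), split = lo + k - 1L)
}

# recursive binary segmentation into piecewise-constant segments
segment_constant <- function(y, penalty, min_len) {
  bounds <- integer(0)  # last index of each completed left segment
  recurse <- function(lo, hi) {
    s <- best_split(y, lo, hi, min_len)
    if (is.null(s) || s$gain <= penalty) return(invisible(NULL))
    recurse(lo, s$split)
    bounds <<- c(bounds, s$split)
    recurse(s$split + 1L, hi)
  }
  recurse(1L, length(y))
  sort(bounds)
}

#' Detect cuticle steps in a line profile
#'
#' Segments the profile into terraces with piecewise-constant change-point
#' detection (binary segmentation minimizing within-segment variance, with a
#' noise-scaled penalty), merges adjacent terraces whose median difference is
#' below `min_height`, and reports one step event per remaining boundary
#' whose flanking terraces are at least `min_terrace` long. The step height
#' is the difference of the flanking terrace medians, which is robust to
#' edge rounding and debris spikes.
#'
#' @param profile A [line_profile()] with at least 8 points.
#' @param min_height Minimum reported step height, nm (> 0).
#' @param min_terrace Minimum flanking terrace length, um.
#' @return Data frame with columns `position` (um), `height` (nm, magnitude)
#'   and `direction` (`"rise"` or `"fall"`). Zero rows for a flat profile.
#' @export
#' @examples
#' img <- gen_topography(topo_truth(roughness_sd = 0, step_height_sd = 0),
#'                       size = c(32, 128), pixel_size = 0.12, seed = 1)
#' detect_steps(extract_profile(img, 16), min_height = 100, min_terrace = 0.5)
detect_steps <- function(profile, min_height = 100, min_terrace = 0.5) {
  stopifnot(inherits(profile, "line_profile"))
  y <- profile$heights
  x <- profile$positions
  if (length(y) < 8L) stop("profile must have >= 8 points", call. = FALSE)
  check_scalar(min_height, "min_height", lower = 0, strict_lower = TRUE)
  check_scalar(min_terrace, "min_terrace", lower = 0)

  px <- mean(diff(x))
  min_len <- max(2L, as.integer(floor(min_terrace / px / 2)))
  sigma <- diff_noise_sd(y)
  # penalty: BIC-like in the noise variance, with an absolute floor so exact
  # (noiseless) terraces are never split on rounding error
  penalty <- max(3 * sigma^2 * log(length(y)), 1e-12 * max(diff(range(y)), 1)^2)
  bounds <- segment_constant(y, penalty, min_len)

  seg_start <- c(1L, bounds + 1L)
  seg_end <- c(bounds, length(y))
  medians <- mapply(function(a, b) stats::median(y[a:b]), seg_start, seg_end)

  # merge adjacent segments whose level difference is below min_height
  repeat {
    if (length(medians) < 2L) break
    diffs <- abs(diff(medians))
    j <- which.min(diffs)
    if (diffs[j] >= min_height) break
    seg_end[j] <- seg_end[j + 1L]
    seg_start <- seg_start[-(j + 1L)]
    seg_end <- seg_end[-(j + 1L)]
    medians <- mapply(function(a, b) stats::median(y[a:b]), seg_start, seg_end)
  }

  if (length(medians) < 2L) {
    return(data.frame(position = numeric(0), height = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  len_um <- (seg_end - seg_start + 1L) * px
  keep <- logical(length(medians) - 1L)
  for (j in seq_along(keep)) {
    keep[j] <- len_um[j] >= min_terrace && len_um[j + 1L] >= min_terrace &&
      abs(medians[j + 1L] - medians[j]) >= min_height
  }
  dh <- diff(medians)[keep]
  pos <- x[seg_end[-length(seg_end)]][keep] + px / 2
  data.frame(position = pos, height = abs(dh),
             direction = ifelse(dh > 0, "rise", "fall"),
             stringsAsFactors = FALSE)
}

#' Summarize step heights across fibers of one group
#'
#' The fiber is the experimental unit: per-fiber step heights are averaged
#' first, then the group mean and SEM are taken over fibers.
#'
#' @param heights Numeric vector of step heights (nm), one entry per detected
#'   step, across all fibers of the group.
#' @param fiber Fiber identifier parallel to `heights`.
#' @param group Dye count of the group (integer).
#' @return A `group_summary` row (see [group_summary()]).
#' @export
#' @examples
#' step_height_summary(c(100, 110, 190, 210), fiber = c(1, 1, 2, 2), group = 0)
step_height_summary <- function(heights, fiber, group = NA_integer_) {
  if (length(heights) != length(fiber)) {
    stop("`heights` and `fiber` must have equal length", call. = FALSE)
  }
  per_fiber <- tapply(heights, fiber, mean)
  group_summary(as.numeric(per_fiber), group = group)
}

#' Areal roughness Sa and Sz
#'
#' After polynomial flattening, `Sa` is the mean absolute deviation of the
#' heights from the mean plane and `Sz` the maximum peak-to-valley height,
#' both over the full sampled area (areal convention). A profile-wise `Sz`
#' (maximum over rows of the per-row peak-to-valley range) is available via
#' `sz_mode = "profile"`.
#'
#' @param image A [topography_image()].
#' @param flatten_order Flattening order applied first (default 1, the mean
#'   plane); use `NA` to skip flattening.
#' @param sz_mode `"areal"` (default) or `"profile"`.
#' @return List with `Sa` (nm), `Sz` (nm), `area` (um x um) and
#'   `flatten_order`.
#' @export
#' @examples
#' roughness(topography_image(matrix(c(0, 2, 4, 6), 2, 2), 1), flatten_order = 0)
roughness <- function(image, flatten_order = 1L, sz_mode = c("areal", "profile")) {
  stopifnot(inherits(image, "topography_image"))
  sz_mode <- match.arg(sz_mode)
  if (length(image$heights) < 4L) stop("image is degenerate", call. = FALSE)
  z <- if (is.na(flatten_order)) image$heights else
    flatten_image(image, flatten_order)$heights
  sa <- mean(abs(z - mean(z)))
  sz <- if (sz_mode == "areal") {
    max(z) - min(z)
  } else {
    max(apply(z, 1L, function(r) max(r) - min(r)))
  }
  d <- dim(z)
  list(Sa = sa, Sz = sz,
       area = c(d[1] * image$pixel_size, d[2] * image$pixel_size),
       flatten_order = if (is.na(flatten_order)) NA_integer_ else
         as.integer(flatten_order))
}

#' Find the flattest window of a given size (single-terrace placement)
#'
#' Slides a candidate window over the image on a coarse grid and returns the
#' crop with the smallest peak-to-valley range after plane flattening. This
#' emulates how a small-area roughness scan is placed on a single cuticle
#' surface, away from scale edges: whenever a step-free placement exists it
#' is preferred, so the small-window roughness reflects the cuticle surface
#' rather than the inter-cuticle steps.
#'
#' @param image A [topography_image()].
#' @param size `(height, width)` of the window, um.
#' @param step Sliding-grid pitch, um (default: a quarter of the window).
#' @param sweep Slide along `"both"` axes or only `"x"` (columns; sufficient
#'   when the staircase runs along the fast-scan axis, with the window
#'   vertically centered).
#' @return The selected cropped [topography_image()], with attribute
#'   `origin` (um).
#' @export
flattest_crop <- function(image, size, step = NULL, sweep = c("both", "x")) {
  stopifnot(inherits(image, "topography_image"))
  sweep <- match.arg(sweep)
  if (length(size) == 1L) size <- c(size, size)
  if (is.null(step)) step <- min(size) / 4
  extent <- (dim(image$heights) - 1L) * image$pixel_size
  if (any(size > extent + 1e-9)) {
    stop("window larger than the image", call. = FALSE)
  }
  ys <- seq(0, extent[1] - size[1], by = step)
  if (sweep == "x") ys <- max((extent[1] - size[1]) / 2, 0)
  xs <- seq(0, extent[2] - size[2], by = step)
  best <- NULL; best_sz <- Inf; best_orig <- c(0, 0)
  for (y in ys) for (x in xs) {
    cr <- crop_image(image, c(y, x), size)
    sz <- roughness(cr, flatten_order = 1L)$Sz
    if (sz < best_sz) {
      best <- cr; best_sz <- sz; best_orig <- c(y, x)
    }
  }
  attr(best, "origin") <- best_orig
  best
}

#' Crop a physical window out of a topography image
#'
#' Selects the sub-grid of pixels whose centers fall inside
#' `[origin, origin + size)` um (row, column order); pixel size is
#' unchanged. Used for two-scale roughness analysis, e.g. a 3 x 3 um^2
#' single-terrace window versus the full step-spanning field.
#'
#' @param image A [topography_image()].
#' @param origin `(y, x)` of the window origin, um.
#' @param size `(height, width)` of the window, um.
#' @return A [topography_image()].
#' @export
crop_image <- function(image, origin, size) {
  stopifnot(inherits(image, "topography_image"))
  if (length(origin) != 2L || length(size) != 2L || any(size <= 0)) {
    stop("`origin` and `size` must be length-2; size > 0", call. = FALSE)
  }
  d <- dim(image$heights)
  px <- image$pixel_size
  extent <- (d - 1L) * px
  if (any(origin < 0) || any(origin + size > extent + 1e-9)) {
    stop("crop window exceeds image bounds", call. = FALSE)
  }
  ri <- which((seq_len(d[1]) - 1L) * px >= origin[1] - 1e-9 &
                (seq_len(d[1]) - 1L) * px <= origin[1] + size[1] + 1e-9)
  ci <- which((seq_len(d[2]) - 1L) * px >= origin[2] - 1e-9 &
                (seq_len(d[2]) - 1L) * px <= origin[2] + size[2] + 1e-9)
  if (length(ri) < 2L || length(ci) < 2L) {
    stop("crop window too small for this pixel size", call. = FALSE)
  }
  topography_image(image$heights[ri, ci, drop = FALSE], px, id = image$id)
}
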