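# Orchestration: simulate a cohort to disk, analyze all four modalities over
# a dataset directory, and produce the dose-response report. Per-fiber
# failures are caught, logged and counted rather than aborting the run.

#' Default analysis parameters
#'
#' @return Named list: `flatten_order` (roughness flattening), `profile_band`
#'   (rows averaged per step profile), `min_step_height` (nm),
#'   `min_terrace` (um), `crop_size` (um, small-area roughness window),
#'   `fit_fraction` (stiffness fit), `baseline_fraction`, `bands` (band
#'   table), `subtract_gauge`.
#' @export
default_analysis_params <- function() {
  list(flatten_order = 1L, profile_band = 5L, min_step_height = 150,
       min_terrace = 1, crop_size = 3, fit_fraction = 0.7,
       baseline_fraction = 0.25, bands = default_bands(),
       subtract_gauge = FALSE)
}

#' Simulate a cohort dataset on disk
#'
#' Thin wrapper over [gen_cohort()]: accepts a [cohort_config()] or the path
#' of a directory to fill with the default six-group cohort.
#'
#' @param config A [cohort_config()], or a character path (then
#'   [default_cohort_config()] is used with `seed` and `n_fibers`).
#' @param seed,n_fibers Used only when `config` is a path.
#' @return The manifest data frame, invisibly.
#' @export
simulate_cohort <- function(config, seed = 1L, n_fibers = 25L) {
  if (is.character(config)) {
    config <- default_cohort_config(config, seed = seed, n_fibers = n_fibers)
  }
  gen_cohort(config)
}

analyze_one_fiber <- function(root, row, params) {
  p <- params
  res <- list(fiber_id = row$fiber_id, dye_count = row$dye_count)

  img <- read_topography(file.path(root, row$topo_file))
  prof <- extract_profile(img, row = nrow(img$heights) %/% 2L,
                          band = p$profile_band)
  steps <- detect_steps(prof, min_height = p$min_step_height,
                        min_terrace = p$min_terrace)
  res$step_height <- if (nrow(steps)) mean(steps$height) else NA_real_
  res$n_steps <- nrow(steps)
  rf <- roughness(img, flatten_order = p$flatten_order)
  res$sa_full <- rf$Sa; res$sz_full <- rf$Sz
  extent <- (dim(img$heights) - 1L) * img$pixel_size
  small <- flattest_crop(img, pmin(c(p$crop_size, p$crop_size), extent),
                         sweep = "x")
  rc <- roughness(small, flatten_order = p$flatten_order)
  res$sa_crop <- rc$Sa; res$sz_crop <- rc$Sz

  fdc <- read_fd_curve(file.path(root, row$fd_file))
  fdf <- fd_features(fdc, fit_fraction = p$fit_fraction,
                     baseline_fraction = p$baseline_fraction)
  res$stiffness <- fdf$stiffness
  res$adhesion <- fdf$adhesion
  res$attraction <- fdf$attraction

  tc <- read_tensile_curve(file.path(root, row$tensile_file),
                           subtract_gauge = p$subtract_gauge)
  tf <- tensile_features(tc)
  res$elastic_modulus <- tf$elastic_modulus
  res$yield_stress <- tf$yield_stress
  res$fracture_stress <- tf$fracture_stress
  res$fracture_strain <- tf$fracture_strain

  sp <- read_spectrum(file.path(root, row$ftir_file))
  bq <- quantify_bands(sp, bands = p$bands)
  for (i in seq_len(nrow(bq))) {
    res[[paste0(bq$name[i], "_depth")]] <- bq$depth[i]
    res[[paste0(bq$name[i], "_present")]] <- bq$present[i]
  }
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Analyze every fiber of a cohort dataset
#'
#' Reads the manifest under `root` and runs all four modality analyzers per
#' fiber. A fiber whose analysis fails (for example a corrupted file) is
#' skipped; the failure is recorded with its error message and counted.
#'
#' @param root Dataset root directory (with `manifest.csv`).
#' @param params Analysis parameters; see [default_analysis_params()].
#' @param quiet Suppress per-failure messages.
#' @return List of class `cohort_analysis`: `features` (one row per analyzed
#'   fiber), `failures` (data frame of fiber id + message), `n_failed`,
#'   `manifest`, `params`.
#' @export
analyze_cohort <- function(root, params = default_analysis_params(),
                           quiet = FALSE) {
  manifest <- read_manifest(root)
  if (!nrow(manifest)) stop("empty dataset: manifest has no rows", call. = FALSE)
  defaults <- default_analysis_params()
  params <- utils::modifyList(defaults, params[intersect(names(params),
                                                         names(defaults))])
  feats <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    out <- tryCatch(analyze_one_fiber(root, row, params), error = function(e) e)
    if (inherits(out, "error")) {
      msg <- conditionMessage(out)
      if (!quiet) message(sprintf("fiber %s failed: %s", row$fiber_id, msg))
      fails[[length(fails) + 1L]] <- data.frame(fiber_id = row$fiber_id,
                                                message = msg,
                                                stringsAsFactors = FALSE)
    } else {
      feats[[length(feats) + 1L]] <- out
    }
  }
  structure(list(features = if (length(feats)) do.call(rbind, feats) else NULL,
                 failures = if (length(fails)) do.call(rbind, fails) else
                   data.frame(fiber_id = character(0), message = character(0)),
                 n_failed = length(fails), manifest = manifest, params = params),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  n_ok <- if (is.null(x$features)) 0L else nrow(x$features)
  cat(sprintf("<cohort_analysis> %d fibers analyzed, %d failed\n",
              n_ok, x$n_failed))
  invisible(x)
}

#' Dose-response report for an analyzed cohort
#'
#' Delegates to [dose_response_report()] with the manifest's truth columns
#' (when present) and optionally writes one CSV per metric, `recovery.csv`
#' and a human-readable `summary.txt` under `output_dir`.
#'
#' @param analysis A `cohort_analysis` from [analyze_cohort()].
#' @param output_dir Optional directory for CSV/text output.
#' @param welch Use Welch's t-test in group comparisons.
#' @return The [dose_response_report()] list, invisibly when writing.
#' @export
report_cohort <- function(analysis, output_dir = NULL, welch = FALSE) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  if (is.null(analysis$features)) stop("no analyzed fibers to report",
                                       call. = FALSE)
  rep <- dose_response_report(analysis$features, manifest = analysis$manifest,
                              welch = welch)
  if (is.null(output_dir)) return(rep)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(rep$tables)) {
    utils::write.csv(rep$tables[[m]],
                     file.path(output_dir, paste0("report_", m, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(rep$recovery)) {
    utils::write.csv(rep$recovery, file.path(output_dir, "recovery.csv"),
                     row.names = FALSE)
  }
  lines <- c("fibremech dose-response report", "")
  for (m in names(rep$tables)) {
    tb <- rep$tables[[m]]
    lines <- c(lines, paste0("== ", m, " =="))
    lines <- c(lines, sprintf(
      "  %2d dyes: n=%d  %10.4g +/- %-9.4g  %+7.1f %%  p=%-9.3g %s",
      tb$group, tb$n, tb$mean, tb$sem, tb$pct_change, tb$p, tb$stars), "")
  }
  if (!is.null(rep$recovery)) {
    worst <- max(abs(rep$recovery$rel_error))
    lines <- c(lines, sprintf(
      "recovery: %d truth-vs-estimate cells, max |relative error| %.2f %%",
      nrow(rep$recovery), 100 * worst))
  }
  writeLines(lines, file.path(output_dir, "summary.txt"))
  invisible(rep)
}
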