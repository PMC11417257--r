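# Plain-text readers/writers for the four modality formats and the cohort
# manifest. All numeric output uses a fixed C-locale format so that repeated
# runs of the generators produce byte-identical files.

fmt_num <- function(x) sprintf("%.8g", x)

#' Write / read a topography image as plain text
#'
#' Format: header lines `# rows R`, `# cols C`, `# pixel_size_um P`, then one
#' whitespace-separated row of heights (nm) per image row.
#'
#' @param image A [topography_image()].
#' @param path File path.
#' @return `write_topography()` returns `path` invisibly; `read_topography()`
#'   returns a [topography_image()].
#' @export
write_topography <- function(image, path) {
  stopifnot(inherits(image, "topography_image"))
  d <- dim(image$heights)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rows %d", d[1]),
               sprintf("# cols %d", d[2]),
               sprintf("# pixel_size_um %s", fmt_num(image$pixel_size))), con)
  writeLines(apply(image$heights, 1L, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop(sprintf("missing '# %s' header in %s", key, path),
                          call. = FALSE)
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1]))
  }
  rows <- as.integer(get("rows")); cols <- as.integer(get("cols"))
  px <- get("pixel_size_um")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) != rows * cols) {
    stop(sprintf("expected %d values, found %d in %s", rows * cols,
                 length(vals), path), call. = FALSE)
  }
  topography_image(matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
                   pixel_size = px, id = basename(path))
}

#' Export / import a topography image as 32-bit float TIFF (heights in nm)
#'
#' Requires the optional `tiff` package.
#'
#' @param image A [topography_image()].
#' @param path File path.
#' @param pixel_size Pixel size in um (TIFF carries no calibrated size here).
#' @return The image (read) or `path` invisibly (write).
#' @export
write_topography_tiff <- function(image, path) {
  stopifnot(inherits(image, "topography_image"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  }
  tiff::writeTIFF(image$heights, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_topography_tiff
#' @export
read_topography_tiff <- function(path, pixel_size) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import", call. = FALSE)
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(m)) m <- m[[1]]
  topography_image(m[, , drop = TRUE] * 1, pixel_size = pixel_size,
                   id = basename(path))
}

#' Write / read a force-distance curve as plain text
#'
#' Format: a `# spring_constant_nN_per_nm` header, then two `# branch` blocks
#' (approach, retract), each with a column-header line
#' `displacement_nm<TAB>force_nN` followed by tab-separated data rows.
#'
#' @param curve An [fd_curve()].
#' @param path File path.
#' @return `write_fd_curve()` returns `path` invisibly; `read_fd_curve()`
#'   returns an [fd_curve()].
#' @export
write_fd_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spring_constant_nN_per_nm %s",
                     fmt_num(curve$spring_constant)), con)
  for (br in c("approach", "retract")) {
    writeLines(c(sprintf("# branch %s", br), "displacement_nm\tforce_nN"), con)
    b <- curve[[br]]
    writeLines(paste(fmt_num(b[, 1]), fmt_num(b[, 2]), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_fd_curve
#' @export
read_fd_curve <- function(path) {
  lines <- readLines(path)
  k_ln <- grep("^# spring_constant_nN_per_nm ", lines, value = TRUE)
  if (!length(k_ln)) stop("missing spring constant header in ", path, call. = FALSE)
  k <- as.numeric(sub("^# spring_constant_nN_per_nm ", "", k_ln[1]))
  starts <- grep("^# branch ", lines)
  if (length(starts) != 2L) stop("expected two '# branch' blocks in ", path,
                                 call. = FALSE)
  names(starts) <- sub("^# branch ", "", lines[starts])
  bounds <- c(starts, length(lines) + 1L)
  parse_block <- function(i) {
    blk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    blk <- blk[!grepl("^#", blk) & nzchar(trimws(blk))]
    blk <- blk[-1L]  # column header line
    m <- matrix(scan(text = paste(blk, collapse = "\n"), quiet = TRUE),
                ncol = 2L, byrow = TRUE)
    m
  }
  blocks <- list(parse_block(1L), parse_block(2L))
  names(blocks) <- names(starts)
  if (!all(c("approach", "retract") %in% names(blocks))) {
    stop("branch blocks must be named approach and retract", call. = FALSE)
  }
  fd_curve(blocks$approach, blocks$retract, spring_constant = k,
           id = basename(path))
}

#' Write / read a tensile curve as plain text
#'
#' Format: `# diameter_um` (and optional `# gauge_force_gf`) headers, a
#' column-header line `strain<TAB>force_mN`, then tab-separated data. Stress
#' is reconstructed on read via [compute_stress()].
#'
#' @param curve A [tensile_curve()].
#' @param path File path.
#' @param subtract_gauge Passed to [tensile_curve()] on read.
#' @return `write_tensile_curve()` returns `path` invisibly;
#'   `read_tensile_curve()` returns a [tensile_curve()].
#' @export
write_tensile_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tensile_curve"))
  area_um2 <- pi * (curve$diameter / 2)^2
  force_mN <- curve$stress * area_um2 * 1e-3
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# diameter_um %s", fmt_num(curve$diameter)), con)
  if (!is.null(curve$gauge_force_gf)) {
    writeLines(sprintf("# gauge_force_gf %s", fmt_num(curve$gauge_force_gf)), con)
  }
  writeLines("strain\tforce_mN", con)
  writeLines(paste(fmt_num(curve$strain), fmt_num(force_mN), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_tensile_curve
#' @export
read_tensile_curve <- function(path, subtract_gauge = FALSE) {
  lines <- readLines(path)
  d_ln <- grep("^# diameter_um ", lines, value = TRUE)
  if (!length(d_ln)) stop("missing diameter header in ", path, call. = FALSE)
  diameter <- as.numeric(sub("^# diameter_um ", "", d_ln[1]))
  g_ln <- grep("^# gauge_force_gf ", lines, value = TRUE)
  gauge <- if (length(g_ln)) as.numeric(sub("^# gauge_force_gf ", "", g_ln[1]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  body <- body[-1L]  # column header
  m <- matrix(scan(text = paste(body, collapse = "\n"), quiet = TRUE),
              ncol = 2L, byrow = TRUE)
  tensile_curve(m[, 1], force_mN = m[, 2], diameter = diameter,
                gauge_force_gf = gauge, subtract_gauge = subtract_gauge,
                id = basename(path))
}

#' Write / read an FT-IR spectrum as plain text
#'
#' Format: one column-header line `wavenumber_cm-1<TAB>transmittance_pct`,
#' then tab-separated data rows.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param path File path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns an [ftir_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavenumber_cm-1\ttransmittance_pct", con)
  writeLines(paste(fmt_num(spectrum$wavenumbers), fmt_num(spectrum$transmittance),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  body <- body[-1L]
  m <- matrix(scan(text = paste(body, collapse = "\n"), quiet = TRUE),
              ncol = 2L, byrow = TRUE)
  ftir_spectrum(m[, 1], m[, 2], id = basename(path))
}

#' Read a JCAMP-DX spectrum (AFFN XYDATA)
#'
#' Minimal reader for uncompressed `##XYDATA=(X++(Y..Y))` blocks with AFFN
#' (plain decimal) values, honoring `XFACTOR`/`YFACTOR`. Intended for real
#' instrument exports; the package's own format is the two-column text of
#' [write_spectrum()].
#'
#' @param path File path.
#' @return An [ftir_spectrum()].
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path)
  get_field <- function(key, default = NA_real_) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(ln)) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", ln[1]))
  }
  xf <- get_field("XFACTOR", 1); yf <- get_field("YFACTOR", 1)
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA block in ", path, call. = FALSE)
  end <- grep("^##END=", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  data_lines <- lines[(start[1] + 1L):(end - 1L)]
  xs <- numeric(0); ys <- numeric(0)
  for (ln in data_lines) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    if (length(vals) < 2L || any(is.na(vals))) next
    x0 <- vals[1] * xf
    yv <- vals[-1] * yf
    # successive Y values advance X by DELTAX; reconstructed from FIRSTX grid
    dx <- get_field("DELTAX", NA_real_)
    if (is.na(dx)) {
      np <- get_field("NPOINTS"); fx <- get_field("FIRSTX") * xf
      lx <- get_field("LASTX") * xf
      dx <- (lx - fx) / (np - 1)
    } else {
      dx <- dx * xf
    }
    xs <- c(xs, x0 + dx * (seq_along(yv) - 1L))
    ys <- c(ys, yv)
  }
  o <- order(xs)
  ftir_spectrum(xs[o], ys[o], id = basename(path))
}
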