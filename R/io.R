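#' Write a spectrum as two-column delimited text
#'
#' Columns are Raman shift (cm^-1) and intensity. Metadata (excitation
#' wavelength, cell id, exposure window, calibration flag) is stored in
#' `#`-prefixed header comments so a file round-trips losslessly.
#'
#' @param s A [raman_spectrum()].
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @export
write_spectrum <- function(s, path, delim = "\t") {
  stopifnot(inherits(s, "raman_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# excitation_nm: %.10g", s$axis$excitation_nm),
    sprintf("# cell_id: %s", s$meta$cell_id),
    sprintf("# exposure_s: %s", paste(s$meta$exposure_s, collapse = " ")),
    sprintf("# substrate: %s", s$meta$substrate),
    sprintf("# calibrated: %s", s$meta$calibrated),
    sprintf("# columns: shift_cm1%sintensity", delim)
  ), con)
  utils::write.table(
    data.frame(shift = format(s$axis$shifts, digits = 17),
               intensity = format(s$intensities, digits = 17)),
    con, sep = delim, quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

read_header_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(sprintf("^#\\s*%s:", key), "", m[1L]))
  }
  list(
    excitation_nm = suppressWarnings(as.numeric(get("excitation_nm"))),
    cell_id = get("cell_id"),
    exposure_s = suppressWarnings(as.numeric(strsplit(get("exposure_s"),
                                                      "\\s+")[[1L]])),
    substrate = get("substrate"),
    calibrated = identical(get("calibrated"), "TRUE")
  )
}

#' Read a two-column delimited spectrum
#'
#' @param path Input file written by [write_spectrum()] or any two-column
#'   (shift, intensity) text file with `#` comments.
#' @param delim Field delimiter; any whitespace if `NULL` (default).
#' @param excitation_nm Excitation wavelength used when the header does not
#'   record one.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, delim = NULL, excitation_nm = 632.8) {
  lines <- readLines(path)
  meta <- read_header_meta(lines)
  if (is.na(meta$excitation_nm)) meta$excitation_nm <- excitation_nm
  dat <- utils::read.table(
    text = lines[!grepl("^#", lines) & nzchar(trimws(lines))],
    sep = if (is.null(delim)) "" else delim
  )
  if (ncol(dat) < 2L) stop("expected two columns (shift, intensity) in ", path)
  ax <- spectral_axis(dat[[1L]], meta$excitation_nm)
  raman_spectrum(ax, dat[[2L]], cell_id = meta$cell_id,
                 exposure_s = if (length(meta$exposure_s) == 2L)
                   meta$exposure_s else c(NA_real_, NA_real_),
                 substrate = meta$substrate, calibrated = meta$calibrated)
}

#' Write a three-frame time series in wide format
#'
#' One shift column plus one intensity column per frame
#' (`frame1`..`frame3`), with the same commented header as
#' [write_spectrum()].
#'
#' @param ts A [timeseries_spectra()].
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @export
write_timeseries <- function(ts, path, delim = "\t") {
  stopifnot(inherits(ts, "timeseries_spectra"))
  con <- file(path, "w")
  on.exit(close(con))
  wins <- vapply(ts$frames, function(f)
    paste(f$meta$exposure_s, collapse = "-"), character(1))
  writeLines(c(
    sprintf("# excitation_nm: %.10g", ts$axis$excitation_nm),
    sprintf("# cell_id: %s", ts$cell_id),
    sprintf("# exposure_windows_s: %s", paste(wins, collapse = " ")),
    sprintf("# columns: shift_cm1%sframe1%sframe2%sframe3",
            delim, delim, delim)
  ), con)
  m <- cbind(ts$axis$shifts,
             vapply(ts$frames, `[[`, numeric(ts$axis$n_pixels), "intensities"))
  utils::write.table(format(m, digits = 17), con, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a wide-format three-frame time series
#'
#' @param path File written by [write_timeseries()] (or any 4-column
#'   shift + 3 frame file).
#' @param delim Field delimiter; any whitespace if `NULL`.
#' @param excitation_nm Fallback excitation wavelength.
#' @return A [timeseries_spectra()].
#' @export
read_timeseries <- function(path, delim = NULL, excitation_nm = 632.8) {
  lines <- readLines(path)
  meta <- read_header_meta(lines)
  if (is.na(meta$excitation_nm)) meta$excitation_nm <- excitation_nm
  dat <- utils::read.table(
    text = lines[!grepl("^#", lines) & nzchar(trimws(lines))],
    sep = if (is.null(delim)) "" else delim
  )
  if (ncol(dat) != 4L) stop("expected 4 columns (shift + 3 frames) in ", path)
  ax <- spectral_axis(dat[[1L]], meta$excitation_nm)
  frames <- lapply(1:3, function(i) {
    raman_spectrum(ax, dat[[i + 1L]], cell_id = meta$cell_id,
                   exposure_s = c((i - 1) * 30, i * 30))
  })
  timeseries_spectra(frames, cell_id = meta$cell_id)
}

#' Read a JCAMP-DX spectrum (XYDATA, fixed-form)
#'
#' Minimal reader for single-block JCAMP-DX files with an
#' `##XYDATA=(X++(Y..Y))` table: X values are reconstructed from FIRSTX /
#' DELTAX (or XFACTOR-scaled leading abscissae) and Y values are scaled by
#' YFACTOR. X units are taken as Raman shift in cm^-1.
#'
#' @param path JCAMP-DX file path.
#' @param excitation_nm Excitation wavelength for the axis (JCAMP files carry
#'   no Raman excitation field in this dialect).
#' @return A [raman_spectrum()].
#' @export
read_jcamp <- function(path, excitation_nm = 632.8) {
  lines <- readLines(path)
  ldr <- function(name, default = NA) {
    m <- grep(sprintf("^##%s=", name), lines, ignore.case = TRUE, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub("^##[^=]*=", "", m[1L]))
  }
  num <- function(name, default = NA_real_) {
    v <- suppressWarnings(as.numeric(ldr(name)))
    if (is.na(v)) default else v
  }
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA= block in ", path)
  start <- start[1L]
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[(start + 1L):end]
  body <- body[nzchar(trimws(body)) & !grepl("^\\$\\$", body)]
  xfac <- num("XFACTOR", 1)
  yfac <- num("YFACTOR", 1)
  xs <- c()
  ys <- c()
  for (ln in body) {
    toks <- as.numeric(strsplit(trimws(ln), "[\\s,;]+", perl = TRUE)[[1L]])
    if (anyNA(toks) || length(toks) < 2L) {
      stop("unparseable XYDATA line in ", path, ": ", ln)
    }
    xs <- c(xs, toks[1L] * xfac)
    ys <- c(ys, toks[-1L] * yfac)
  }
  npt <- num("NPOINTS", length(ys))
  if (npt != length(ys)) {
    stop("NPOINTS (", npt, ") != number of Y values (", length(ys), ")")
  }
  firstx <- num("FIRSTX", xs[1L])
  lastx <- num("LASTX", NA_real_)
  deltax <- num("DELTAX", if (!is.na(lastx)) (lastx - firstx) / (npt - 1)
                else NA_real_)
  if (is.na(deltax)) stop("cannot determine DELTAX in ", path)
  x <- firstx + deltax * (seq_len(npt) - 1L)
  if (deltax < 0) { # descending table; axis wants ascending shifts
    x <- rev(x)
    ys <- rev(ys)
  }
  ax <- spectral_axis(x, excitation_nm)
  raman_spectrum(ax, ys, cell_id = ldr("TITLE", NA_character_))
}

#' Export per-cell records as CSV
#'
#' @param records A data.frame of per-cell descriptors (see
#'   [quantify_cells()]).
#' @param path Output CSV path.
#' @export
write_cell_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell record CSV
#'
#' @param path CSV written by [write_cell_records()].
#' @return A data.frame.
#' @export
read_cell_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Append structured log records as JSON lines
#'
#' One JSON object per line; used for per-cell rejection and processing logs.
#'
#' @param entries A list of named lists (one per record) or a data.frame.
#' @param path Output file; appended to if it exists.
#' @export
write_jsonl <- function(entries, path) {
  if (is.data.frame(entries)) {
    entries <- lapply(seq_len(nrow(entries)), function(i) as.list(entries[i, ]))
  }
  con <- file(path, "a")
  on.exit(close(con))
  for (e in entries) {
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  }
  invisible(path)
}
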