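#' FT-IR spectrum container
#'
#' A spectrum is a pair of equal-length numeric vectors — wavenumbers in
#' cm^-1 (stored strictly descending, conventionally 3600 to 800) and
#' dimensionless absorbances — plus a processing-state flag tracking the
#' pipeline stage (`raw`, `baseline_corrected`, `averaged`, `normalized`)
#' and free-form acquisition metadata (group label, replicate id).
#'
#' @param wavenumbers Numeric vector, cm^-1. Re-sorted descending;
#'   duplicates are an error.
#' @param absorbances Numeric vector, same length as `wavenumbers`.
#' @param state Processing state, one of `"raw"`, `"baseline_corrected"`,
#'   `"averaged"`, `"normalized"`.
#' @param meta Named list of acquisition labels.
#' @return An object of class `ftir_spectrum`.
#' @export
#' @examples
#' s <- spectrum(seq(3600, 800, by = -4), rep(0.5, 701))
#' s
spectrum <- function(wavenumbers, absorbances,
                     state = c("raw", "baseline_corrected", "averaged", "normalized"),
                     meta = list()) {
  state <- match.arg(state)
  wavenumbers <- as.numeric(wavenumbers)
  absorbances <- as.numeric(absorbances)
  if (length(wavenumbers) != length(absorbances)) {
    stop("wavenumber/absorbance length mismatch (", length(wavenumbers),
         " vs ", length(absorbances), ")")
  }
  if (length(wavenumbers) < 2L) stop("a spectrum needs at least 2 points")
  if (anyNA(wavenumbers) || anyNA(absorbances)) stop("missing values in spectrum")
  ord <- order(wavenumbers, decreasing = TRUE)
  wavenumbers <- wavenumbers[ord]
  absorbances <- absorbances[ord]
  if (anyDuplicated(wavenumbers)) stop("duplicate wavenumbers")
  structure(
    list(wavenumbers = wavenumbers, absorbances = absorbances,
         state = state, meta = meta),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %d points, %.0f-%.0f cm^-1, state: %s\n",
              length(x$wavenumbers), max(x$wavenumbers), min(x$wavenumbers),
              x$state))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "ftir_spectrum")

stopifnot_spectrum <- function(s) {
  if (!is_spectrum(s)) stop("expected an `ftir_spectrum` object")
  invisible(s)
}

grid_step <- function(s) {
  # median spacing; robust to a non-uniform grid
  stats::median(abs(diff(s$wavenumbers)))
}

#' Read a spectrum from disk
#'
#' Supports two plain-text formats: two-column CSV (header line, columns
#' wavenumber then absorbance) and JCAMP-DX with an `##XYDATA=(XY..XY)`
#' block. Wavenumbers are re-sorted descending; duplicates are rejected.
#'
#' @param path File path.
#' @param format `"csv"` or `"jcamp"`.
#' @param meta Optional metadata list attached to the spectrum.
#' @return An `ftir_spectrum` in `raw` state.
#' @export
read_spectrum <- function(path, format = c("csv", "jcamp"), meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  xy <- switch(format,
    csv = read_spectrum_csv(path),
    jcamp = read_spectrum_jcamp(path)
  )
  spectrum(xy$x, xy$y, state = "raw", meta = meta)
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("format error in ", path, ": no data lines")
  body <- lines[-1L]                       # header line skipped
  parts <- strsplit(body, ",", fixed = TRUE)
  n_col <- lengths(parts)
  if (any(n_col != 2L)) {
    bad <- which(n_col != 2L)[1L]
    stop("format error in ", path, " line ", bad + 1L, ": expected 2 columns")
  }
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(x) || anyNA(y)) {
    bad <- which(is.na(x) | is.na(y))[1L]
    stop("format error in ", path, " line ", bad + 1L, ": non-numeric value")
  }
  list(x = x, y = y)
}

#' Write a spectrum to disk
#'
#' @param s An `ftir_spectrum`.
#' @param path Output file path.
#' @param format `"csv"` (two columns, header) or `"jcamp"`
#'   (JCAMP-DX `(XY..XY)` table).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("csv", "jcamp")) {
  stopifnot_spectrum(s)
  format <- match.arg(format)
  if (format == "csv") {
    lines <- c("wavenumber,absorbance",
               sprintf("%.8g,%.8g", s$wavenumbers, s$absorbances))
  } else {
    title <- if (!is.null(s$meta$title)) s$meta$title else "methylscope spectrum"
    lines <- c(
      paste0("##TITLE=", title),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      paste0("##NPOINTS=", length(s$wavenumbers)),
      "##XYDATA=(XY..XY)",
      sprintf("%.8g, %.8g", s$wavenumbers, s$absorbances),
      "##END="
    )
  }
  writeLines(lines, path)
  invisible(path)
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^##XYDATA", lines)
  if (length(start) != 1L) stop("format error in ", path, ": no ##XYDATA block")
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start]) else length(lines) + 1L
  body <- lines[seq(start + 1L, end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("format error in ", path, ": empty XYDATA block")
  parts <- strsplit(body, "[,;[:space:]]+")
  parts <- lapply(parts, function(p) p[nzchar(p)])
  if (any(lengths(parts) != 2L)) {
    bad <- which(lengths(parts) != 2L)[1L]
    stop("format error in ", path, " line ", start + bad, ": expected an X,Y pair")
  }
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(x) || anyNA(y)) {
    bad <- which(is.na(x) | is.na(y))[1L]
    stop("format error in ", path, " line ", start + bad, ": non-numeric value")
  }
  list(x = x, y = y)
}

#' Absorbance at a target wavenumber
#'
#' Returns the absorbance at the grid point nearest `target`; an exact
#' midpoint tie resolves to the higher wavenumber.
#'
#' @param s An `ftir_spectrum`.
#' @param target Wavenumber, cm^-1; must lie within the spectral range.
#' @return Scalar absorbance.
#' @export
absorbance_at <- function(s, target) {
  stopifnot_spectrum(s)
  rng <- range(s$wavenumbers)
  if (target < rng[1L] || target > rng[2L]) {
    stop("target ", target, " cm^-1 outside spectral range [",
         rng[1L], ", ", rng[2L], "]")
  }
  d <- abs(s$wavenumbers - target)
  # wavenumbers are stored descending, so which.min's first-match rule
  # already awards ties to the higher wavenumber
  s$absorbances[which.min(d)]
}

#' Extract a wavenumber window
#'
#' Sub-spectrum of the grid points with `lo <= wavenumber <= hi`
#' (closed interval). The processing state is preserved.
#'
#' @param s An `ftir_spectrum` (any post-raw state; windowing a raw
#'   spectrum is refused to keep the processing order explicit).
#' @param hi,lo Window edges in cm^-1, `hi > lo`.
#' @return An `ftir_spectrum` restricted to the window.
#' @export
extract_window <- function(s, hi, lo) {
  stopifnot_spectrum(s)
  if (s$state == "raw") {
    stop("window extraction expects a corrected spectrum; run baseline_correct() first")
  }
  if (!(hi > lo)) stop("window edges must satisfy hi > lo")
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (!any(keep)) stop("empty window: no grid points in [", lo, ", ", hi, "]")
  out <- s
  out$wavenumbers <- s$wavenumbers[keep]
  out$absorbances <- s$absorbances[keep]
  out
}
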