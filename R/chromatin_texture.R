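# Feulgen image-cytometry texture statistics. A digitized nucleus is a
# per-pixel absorbance map; pixels at or below the removal floor (0.020)
# are discarded, pixels at or above the condensation cutoff (0.100) are
# scored as condensed chromatin, and the texture is summarized by the
# condensed area fraction S_C% and the average absorption ratio
# AAR = (A_C/S_C) / (A_T/S_T).

#' Absorbance image container
#'
#' @param values Numeric matrix of per-pixel absorbances (finite, >= 0).
#' @param pixel_um Side of a square pixel in micrometres (default 0.5,
#'   i.e. 0.25 um^2 per pixel).
#' @return An `absorbance_image`.
#' @export
absorbance_image <- function(values, pixel_um = 0.5) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) stop("non-finite absorbance values")
  if (any(values < 0)) stop("negative absorbance values")
  if (pixel_um <= 0) stop("pixel_um must be > 0")
  structure(list(values = values, pixel_um = pixel_um),
            class = "absorbance_image")
}

#' @export
print.absorbance_image <- function(x, ...) {
  cat(sprintf("<absorbance_image> %d x %d px, %.2f um/px, absorbance %.3f-%.3f\n",
              nrow(x$values), ncol(x$values), x$pixel_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read an absorbance map from a plain-matrix CSV or float TIFF
#'
#' @param path File path; `.csv` files are headerless numeric matrices,
#'   anything else is read as TIFF.
#' @param pixel_um Pixel side, micrometres.
#' @return An [absorbance_image()].
#' @export
read_absorbance_image <- function(path, pixel_um = 0.5) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    values <- as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    values <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(values)) == 3L) values <- values[, , 1L]
  }
  dimnames(values) <- NULL
  absorbance_image(values, pixel_um = pixel_um)
}

#' Write an absorbance map
#'
#' @param img An [absorbance_image()].
#' @param path Output path; `.csv` for a plain matrix, otherwise a
#'   32-bit float TIFF.
#' @return `path`, invisibly.
#' @export
write_absorbance_image <- function(img, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.table(img$values, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    tiff::writeTIFF(img$values, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Nuclear pixel mask
#'
#' Pixels with absorbance **strictly greater** than the removal floor
#' belong to the nucleus; measuring points at or below the floor are
#' treated as automatically removed.
#'
#' @param img An [absorbance_image()].
#' @param removal_floor Absorbance floor, default 0.020.
#' @return Logical matrix.
#' @export
nuclear_mask <- function(img, removal_floor = 0.020) {
  if (!inherits(img, "absorbance_image")) stop("expected an `absorbance_image`")
  mask <- img$values > removal_floor
  if (!any(mask)) stop("no nuclear signal: every pixel at or below the removal floor")
  mask
}

#' Condensed-chromatin pixel mask
#'
#' Subset of the nuclear mask with absorbance at or above the
#' condensation cutoff. The comparison is `>=` so the cutoff value
#' itself scores as condensed; an empty result is a valid outcome
#' (fully decondensed nucleus).
#'
#' @param img An [absorbance_image()].
#' @param cutoff Condensation cutoff, default 0.100.
#' @param mask Nuclear mask (from [nuclear_mask()]).
#' @return Logical matrix.
#' @export
condensed_mask <- function(img, cutoff = 0.100, mask = nuclear_mask(img)) {
  if (!any(mask)) stop("empty nuclear mask")
  mask & img$values >= cutoff
}

#' Measure one nucleus
#'
#' Computes the cytometry quartet and derived texture statistics:
#' total nuclear area `S_T` (pixel count times pixel area, um^2),
#' condensed area `S_C`, integrated absorbances `A_T` and `A_C`,
#' the condensed area fraction `Sc_percent = 100 * S_C / S_T` and the
#' average absorption ratio `AAR = (A_C/S_C) / (A_T/S_T)` — the mean
#' absorbance of condensed chromatin relative to that of the whole
#' nucleus. With no condensed pixels `Sc_percent` is 0 and `AAR` is
#' undefined (`NA`), never 0 or infinity.
#'
#' @param img An [absorbance_image()].
#' @param removal_floor Absorbance removal floor, default 0.020.
#' @param cutoff Condensation cutoff, default 0.100.
#' @return A `nucleus_measurement` list with fields `S_T`, `S_C`,
#'   `A_T`, `A_C`, `Sc_percent`, `AAR`, `removal_floor`, `cutoff`.
#' @export
#' @examples
#' img <- absorbance_image(matrix(c(0.05, 0.08, 0.15, 0.25), 2), pixel_um = 0.5)
#' m <- measure_nucleus(img)
#' m$Sc_percent  # 50
#' m$AAR         # (0.40/0.5) / (0.53/1.0) = 1.5094
measure_nucleus <- function(img, removal_floor = 0.020, cutoff = 0.100) {
  nmask <- nuclear_mask(img, removal_floor)
  cmask <- condensed_mask(img, cutoff, nmask)
  px_area <- img$pixel_um^2
  S_T <- sum(nmask) * px_area
  A_T <- sum(img$values[nmask])
  S_C <- sum(cmask) * px_area
  A_C <- if (any(cmask)) sum(img$values[cmask]) else 0
  Sc_percent <- 100 * S_C / S_T
  AAR <- if (S_C > 0) (A_C / S_C) / (A_T / S_T) else NA_real_
  structure(list(S_T = S_T, S_C = S_C, A_T = A_T, A_C = A_C,
                 Sc_percent = Sc_percent, AAR = AAR,
                 removal_floor = removal_floor, cutoff = cutoff),
            class = "nucleus_measurement")
}

#' @export
print.nucleus_measurement <- function(x, ...) {
  cat(sprintf("<nucleus_measurement> S_T %.2f um^2, S_C %.2f um^2, S_C%% %.1f, AAR %s\n",
              x$S_T, x$S_C, x$Sc_percent,
              if (is.na(x$AAR)) "NA" else sprintf("%.4f", x$AAR)))
  invisible(x)
}

#' Measure a batch of nuclei
#'
#' One measurement row per image, tagged with a group label and source
#' id; ready for an S_C% vs AAR scatter. Per-image failures (e.g. no
#' pixel above the removal floor) are collected and reported as a
#' warning, not fatal to the batch.
#'
#' @param images List of [absorbance_image()] objects (or
#'   `nucleus_simulation` objects, whose `$image` is used). Names become
#'   ids; unnamed entries are numbered.
#' @param group_label Group tag added to every row.
#' @param removal_floor,cutoff Passed to [measure_nucleus()].
#' @return A data.frame with columns `id`, `group`, `S_T_um2`,
#'   `S_C_um2`, `A_T`, `A_C`, `Sc_percent`, `AAR`. Failed images are
#'   recorded in the `"failures"` attribute.
#' @export
batch_measure <- function(images, group_label,
                          removal_floor = 0.020, cutoff = 0.100) {
  if (!length(images)) stop("no images")
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("nucleus_%03d", seq_along(images))
  rows <- vector("list", length(images))
  failures <- character(0)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (inherits(img, "nucleus_simulation")) img <- img$image
    m <- tryCatch(measure_nucleus(img, removal_floor, cutoff),
                  error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures, paste0(ids[i], ": ", conditionMessage(m)))
      next
    }
    rows[[i]] <- data.frame(id = ids[i], group = group_label,
                            S_T_um2 = m$S_T, S_C_um2 = m$S_C,
                            A_T = m$A_T, A_C = m$A_C,
                            Sc_percent = m$Sc_percent, AAR = m$AAR,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("all images failed: ", paste(failures, collapse = "; "))
  rownames(out) <- NULL
  if (length(failures)) {
    warning(length(failures), " image(s) failed: ",
            paste(failures, collapse = "; "))
  }
  attr(out, "failures") <- failures
  out
}

#' Texture scatter plot (S_C% vs AAR)
#'
#' The classic chromatin-condensation scatter: decreased S_C% with
#' increased AAR marks decondensation.
#'
#' @param measurements Output of [batch_measure()] (rows from several
#'   groups may be combined with `rbind`).
#' @return A ggplot object.
#' @export
plot_texture_scatter <- function(measurements) {
  df <- measurements[!is.na(measurements$AAR), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = Sc_percent, y = AAR, colour = group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = expression(S[C] ~ "%"), y = "AAR", colour = "group") +
    ggplot2::theme_classic()
}
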