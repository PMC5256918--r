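# Per-nucleus 5mC immunofluorescence quantification on the 8-bit
# intensity scale: threshold segmentation, background-corrected mean
# intensities, and gridded intensity surfaces for 3D display.

#' Fluorescence image container
#'
#' @param values Integer matrix with values in 0-255.
#' @param masks Optional list of logical nucleus masks.
#' @param meta Named list; `group` and `exposure` tags are used by the
#'   comparability checks.
#' @return A `fluorescence_image`.
#' @export
fluorescence_image <- function(values, masks = NULL, meta = list()) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing intensity values")
  if (any(values < 0 | values > 255)) stop("intensities must lie in [0, 255]")
  if (any(values != round(values))) stop("intensities must be integers (8-bit scale)")
  structure(list(values = values, masks = masks, meta = meta),
            class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("<fluorescence_image> %d x %d px, range %d-%d, %d mask(s)\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              length(x$masks)))
  invisible(x)
}

#' Read / write 8-bit grayscale images
#'
#' @param path File path; `.png` is handled by the png package,
#'   anything else as TIFF.
#' @param meta Metadata attached to the image.
#' @return [read_fluorescence_image()]: a `fluorescence_image`.
#' @export
read_fluorescence_image <- function(path, meta = list()) {
  raw <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  fluorescence_image(round(raw * 255), meta = meta)
}

#' @rdname read_fluorescence_image
#' @param img A `fluorescence_image`.
#' @export
write_fluorescence_image <- function(img, path) {
  scaled <- img$values / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(scaled, path)
  } else {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Segment nuclei by thresholding and connected components
#'
#' Above-threshold pixels are labeled by 4/8-connectivity and components
#' smaller than `min_size` pixels are dropped. Touching nuclei merge
#' into a single component — a documented limitation of threshold
#' segmentation. Masks are returned in deterministic row-major centroid
#' order.
#'
#' @param img A `fluorescence_image`.
#' @param threshold Numeric intensity in 0-255, or `"otsu"` for an
#'   automatic Otsu threshold.
#' @param min_size Minimum component size in pixels (default 50).
#' @return List of logical masks (possibly empty).
#' @export
segment_nuclei <- function(img, threshold = "otsu", min_size = 50L) {
  if (!inherits(img, "fluorescence_image")) stop("expected a `fluorescence_image`")
  v <- img$values / 255
  thr <- if (identical(threshold, "otsu")) {
    if (length(unique(as.vector(v))) < 2L) {
      return(list())  # constant image: nothing to segment
    }
    EBImage::otsu(v, range = c(0, 1))
  } else {
    as.numeric(threshold) / 255
  }
  bin <- v > thr
  if (!any(bin)) return(list())
  labels <- EBImage::bwlabel(bin)
  n_lab <- max(labels)
  if (n_lab == 0L) return(list())
  masks <- list()
  centroids <- matrix(numeric(0), ncol = 2)
  for (l in seq_len(n_lab)) {
    m <- labels == l
    if (sum(m) < min_size) next
    idx <- which(m, arr.ind = TRUE)
    masks[[length(masks) + 1L]] <- m
    centroids <- rbind(centroids, colMeans(idx))
  }
  if (!length(masks)) return(list())
  ord <- order(centroids[, 1L], centroids[, 2L])
  masks[ord]
}

#' Per-nucleus mean intensity
#'
#' Arithmetic mean of the pixel values inside each mask, optionally
#' minus a background estimate (the median intensity of the pixels
#' outside every mask). With correction off, values match a plain
#' region mean as reported by standard image-analysis software.
#'
#' @param img A `fluorescence_image`.
#' @param masks List of logical masks (defaults to the image's own).
#' @param background_correct Subtract the median non-mask intensity?
#' @return Numeric vector of mean intensities, one per mask.
#' @export
mean_nuclear_intensity <- function(img, masks = img$masks,
                                   background_correct = TRUE) {
  if (!inherits(img, "fluorescence_image")) stop("expected a `fluorescence_image`")
  if (is.null(masks) || !length(masks)) stop("no masks supplied")
  for (m in masks) {
    if (!identical(base::dim(m), base::dim(img$values))) stop("mask outside image bounds")
    if (!any(m)) stop("empty mask")
  }
  means <- vapply(masks, function(m) mean(img$values[m]), numeric(1))
  if (background_correct) {
    outside <- !Reduce(`|`, masks)
    bg <- if (any(outside)) stats::median(img$values[outside]) else 0
    means <- means - bg
  }
  means
}

#' Gridded intensity surface
#'
#' Long-format (x, y, intensity) table of a downsampled copy of the
#' image, suitable for 3D surface display of the fluorescence signal.
#' Values are untouched; downsampling keeps every `factor`-th pixel.
#'
#' @param img A `fluorescence_image`.
#' @param factor Positive integer downsampling factor; 1 keeps every
#'   pixel.
#' @return Data.frame with columns `x` (column), `y` (row),
#'   `intensity`.
#' @export
intensity_surface <- function(img, factor = 1L) {
  if (!inherits(img, "fluorescence_image")) stop("expected a `fluorescence_image`")
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  rows <- seq(1L, nrow(img$values), by = factor)
  cols <- seq(1L, ncol(img$values), by = factor)
  sub <- img$values[rows, cols, drop = FALSE]
  data.frame(
    x = rep(cols, each = length(rows)),
    y = rep(rows, times = length(cols)),
    intensity = as.vector(sub)
  )
}

#' Batch per-nucleus intensity table
#'
#' Segments (or reuses ground-truth masks of) each image and tabulates
#' per-nucleus areas and mean intensities. All images must carry the
#' same `exposure` tag: intensities acquired under different exposure
#' conditions are not comparable and mixing them is an error.
#'
#' @param images List of `fluorescence_image` objects.
#' @param group_labels Character vector of group tags, one per image
#'   (or a single tag recycled).
#' @param use_truth_masks Use the images' own ground-truth masks when
#'   present instead of re-segmenting.
#' @param threshold,min_size,background_correct Passed through.
#' @return Data.frame with columns `id`, `group`, `nucleus`, `area_px`,
#'   `mean_intensity`.
#' @export
if_measure_batch <- function(images, group_labels,
                             use_truth_masks = TRUE,
                             threshold = "otsu", min_size = 50L,
                             background_correct = TRUE) {
  if (!length(images)) stop("no images")
  group_labels <- rep_len(group_labels, length(images))
  exposures <- vapply(images, function(im) {
    e <- im$meta$exposure
    if (is.null(e)) NA_character_ else as.character(e)
  }, character(1))
  if (length(unique(exposures)) > 1L) {
    stop("mixed exposure tags (", paste(unique(exposures), collapse = ", "),
         "): group comparisons require identical exposure conditions")
  }
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
  rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    masks <- if (use_truth_masks && !is.null(img$masks) && length(img$masks)) {
      img$masks
    } else {
      segment_nuclei(img, threshold, min_size)
    }
    if (!length(masks)) next
    means <- mean_nuclear_intensity(img, masks, background_correct)
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids[i], group = group_labels[i],
      nucleus = seq_along(masks),
      area_px = vapply(masks, sum, numeric(1)),
      mean_intensity = means, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no nuclei found in any image")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
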