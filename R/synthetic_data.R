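# Seeded generators for the three assay arms. Each emits ground truth
# (masks, band parameters, realized fractions) so downstream measurement
# code has a recovery-based test surface.

#' Gaussian band profile and closed-form area
#'
#' Bands are Gaussians parameterized by full width at half maximum:
#' `h * exp(-4 ln2 ((x - c)/fwhm)^2)`, whose analytic area is
#' `h * fwhm * sqrt(pi / (4 ln2))`.
#'
#' @param x Wavenumbers, cm^-1.
#' @param center Band center, cm^-1.
#' @param height Peak height, absorbance.
#' @param fwhm Full width at half maximum, cm^-1.
#' @return `gaussian_profile()`: absorbance at `x`; `gaussian_area()`:
#'   the analytic band area (absorbance * cm^-1).
#' @export
gaussian_profile <- function(x, center, height, fwhm) {
  height * exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

#' @rdname gaussian_profile
#' @export
gaussian_area <- function(height, fwhm) {
  height * fwhm * sqrt(pi / (4 * log(2)))
}

#' Specify a synthetic IR band
#'
#' @param center Band center, cm^-1; must lie in 800-3600.
#' @param height Peak height, absorbance, > 0.
#' @param fwhm Full width at half maximum, cm^-1, > 0.
#' @param assignment Free-text vibrational assignment label.
#' @param methylation_scaled If `TRUE` the band height is multiplied by
#'   the generator's methylation level, emulating a 5mC-sensitive band.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, height, fwhm, assignment = "",
                      methylation_scaled = FALSE) {
  if (center < 800 || center > 3600) {
    stop("band center ", center, " cm^-1 outside 3600-800 cm^-1")
  }
  if (height <= 0) stop("band height must be > 0")
  if (fwhm <= 0) stop("band fwhm must be > 0")
  structure(list(center = center, height = height, fwhm = fwhm,
                 assignment = assignment,
                 methylation_scaled = isTRUE(methylation_scaled)),
            class = "band_spec")
}

#' Default synthetic DNA band library
#'
#' Eight Gaussian bands at the centers characteristic of B-form DNA
#' absorption: NH/NH2 stretching (3410 cm^-1, the global maximum),
#' CH3 stretching (2935 cm^-1, methylation-scaled), the base-pairing
#' carbonyl shoulder (1707), thymine/adenine ring modes (1661), cytosine
#' in-plane vibrations (1492), CH3 bending (1375, methylation-scaled),
#' antisymmetric phosphate stretching (1225, the B-form marker) and
#' symmetric phosphate stretching (1080, lower than the 1225 band).
#' Heights and widths are generator defaults chosen to give a plausible
#' DNA-like profile; they are not instrument-derived values.
#'
#' @return List of [band_spec()] objects.
#' @export
#' @examples
#' lib <- default_dna_band_library()
#' vapply(lib, `[[`, numeric(1), "center")
default_dna_band_library <- function() {
  list(
    band_spec(3410, 1.00, 200, "NH/NH2 stretching + H bonding"),
    band_spec(2935, 0.35, 45, "CH3 stretching (nu_as/nu_s C-H)",
              methylation_scaled = TRUE),
    band_spec(1707, 0.30, 40, "base-pairing carbonyl shoulder"),
    band_spec(1661, 0.55, 50, "thymine/adenine contribution"),
    band_spec(1492, 0.30, 25, "cytosine in-plane vibration"),
    band_spec(1375, 0.33, 25, "CH3 bending",
              methylation_scaled = TRUE),
    band_spec(1225, 0.50, 50, "nu_as PO2- (B-form marker)"),
    band_spec(1080, 0.40, 45, "nu_s PO2-")
  )
}

#' Simulate an FT-IR DNA spectrum
#'
#' Absorbance is the sum of Gaussian bands (heights of
#' methylation-scaled bands multiplied by `methylation_level`), a
#' polynomial baseline, and additive Gaussian noise, evaluated on a
#' descending wavenumber grid.
#'
#' @param methylation_level Real in `[0, 1]`; scales flagged bands.
#' @param bands List of [band_spec()]; default [default_dna_band_library()].
#' @param baseline_coeffs Polynomial coefficients (intercept first), in
#'   absorbance per power of cm^-1.
#' @param noise_sd Additive Gaussian noise SD, absorbance.
#' @param wavenumber_range High/low grid bounds, cm^-1.
#' @param resolution Grid spacing, cm^-1.
#' @param seed Integer seed; spectra are reproducible given the seed.
#' @param meta Metadata list passed to the spectrum.
#' @return An `ftir_spectrum` in `raw` state. The noiseless band-only
#'   component is attached as attribute `"truth"` for recovery tests.
#' @export
generate_ftir_spectrum <- function(methylation_level,
                                   bands = default_dna_band_library(),
                                   baseline_coeffs = 0,
                                   noise_sd = 0,
                                   wavenumber_range = c(3600, 800),
                                   resolution = 4,
                                   seed = NULL,
                                   meta = list()) {
  if (!length(bands)) stop("no bands")
  if (methylation_level < 0 || methylation_level > 1) {
    stop("methylation_level must be in [0, 1]")
  }
  if (resolution <= 0) stop("resolution must be > 0")
  hi <- max(wavenumber_range); lo <- min(wavenumber_range)
  wn <- seq(hi, lo, by = -resolution)
  signal <- rep(0, length(wn))
  for (b in bands) {
    h <- b$height * if (b$methylation_scaled) methylation_level else 1
    signal <- signal + gaussian_profile(wn, b$center, h, b$fwhm)
  }
  baseline <- rep(0, length(wn))
  for (k in seq_along(baseline_coeffs)) {
    baseline <- baseline + baseline_coeffs[k] * wn^(k - 1)
  }
  noise <- if (noise_sd > 0) {
    if (is.null(seed)) rnorm(length(wn), 0, noise_sd) else
      withr::with_seed(seed, rnorm(length(wn), 0, noise_sd))
  } else rep(0, length(wn))
  s <- spectrum(wn, signal + baseline + noise, state = "raw", meta = meta)
  attr(s, "truth") <- list(signal = signal, baseline = baseline,
                           methylation_level = methylation_level)
  s
}

#' Simulate a Feulgen-stained nuclear absorbance map
#'
#' Draws a circular nucleus on a zero background. Inside the nucleus,
#' compact condensed-chromatin blobs at `condensed_level` are placed by
#' rejection sampling of non-overlapping disks until the requested area
#' fraction is met; the last blob is trimmed (farthest pixels first) so
#' the realized pixel count matches the target exactly, and single-pixel
#' fill is used as a fallback once dense packings stop accepting disks.
#' Remaining nuclear pixels sit at `diffuse_level`. Additive Gaussian
#' noise is truncated at zero absorbance.
#'
#' @param condensed_fraction Target fraction of nuclear area occupied by
#'   condensed blobs, in `[0, 1]`.
#' @param radius_um Nuclear radius, micrometres.
#' @param diffuse_level Absorbance of diffuse chromatin (> 0.020 so the
#'   nucleus survives the removal floor).
#' @param condensed_level Absorbance of condensed chromatin
#'   (> `diffuse_level`).
#' @param noise_sd Additive Gaussian noise SD, absorbance.
#' @param pixel_um Pixel side, micrometres; the default 0.5 matches the
#'   scanning-spot geometry the cytometry statistics assume.
#' @param blob_radius_px Range of condensed-blob radii, pixels.
#' @param seed Integer seed.
#' @param recoverable If `TRUE` (default), require
#'   `condensed_level > 0.100` and `diffuse_level <= 0.100` so that the
#'   standard cutoff can recover the ground truth.
#' @return A `nucleus_simulation` list: `image` (an [absorbance_image()]),
#'   logical `nuclear_mask` and `condensed_mask` ground-truth matrices,
#'   `realized_fraction` (condensed pixels / nuclear pixels, exact), and
#'   the parameters used.
#' @export
generate_nuclear_absorbance_map <- function(condensed_fraction,
                                            radius_um = 8,
                                            diffuse_level = 0.06,
                                            condensed_level = 0.25,
                                            noise_sd = 0,
                                            pixel_um = 0.5,
                                            blob_radius_px = c(2, 5),
                                            seed = NULL,
                                            recoverable = TRUE) {
  if (condensed_fraction < 0 || condensed_fraction > 1) {
    stop("condensed_fraction must be in [0, 1]")
  }
  if (diffuse_level <= 0.020) stop("diffuse_level must exceed the 0.020 removal floor")
  if (condensed_level <= diffuse_level) stop("condensed_level must exceed diffuse_level")
  if (recoverable && !(condensed_level > 0.100 && diffuse_level <= 0.100)) {
    stop("recoverable simulation requires condensed_level > 0.100 and diffuse_level <= 0.100")
  }
  r_px <- radius_um / pixel_um
  n <- 2L * ceiling(r_px) + 5L
  cx <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  nuclear <- (xs - cx)^2 + (ys - cx)^2 <= r_px^2
  n_nuc <- sum(nuclear)
  target <- round(condensed_fraction * n_nuc)

  build <- function() {
    cond <- matrix(FALSE, n, n)
    count <- 0L
    rejects <- 0L
    nuc_idx <- which(nuclear)
    while (count < target && rejects < 200L) {
      r_blob <- runif(1, blob_radius_px[1L], blob_radius_px[2L])
      ctr <- nuc_idx[sample.int(length(nuc_idx), 1L)]
      bi <- ((ctr - 1L) %% n) + 1L   # row
      bj <- ((ctr - 1L) %/% n) + 1L  # col
      d2 <- (ys - bi)^2 + (xs - bj)^2
      disk <- d2 <= r_blob^2 & nuclear
      if (!any(disk) || any(disk & cond)) { rejects <- rejects + 1L; next }
      idx <- which(disk)
      if (count + length(idx) > target) {
        # trim farthest pixels so the realized count is exact
        keep_n <- target - count
        idx <- idx[order(d2[idx])][seq_len(keep_n)]
      }
      cond[idx] <- TRUE
      count <- count + length(idx)
      rejects <- 0L
    }
    if (count < target) {
      # dense packing: fill remaining diffuse pixels one by one
      free <- which(nuclear & !cond)
      pick <- free[sample.int(length(free), target - count)]
      cond[pick] <- TRUE
    }
    values <- matrix(0, n, n)
    values[nuclear] <- diffuse_level
    values[cond] <- condensed_level
    if (noise_sd > 0) {
      values[nuclear] <- pmax(0, values[nuclear] + rnorm(n_nuc, 0, noise_sd))
    }
    list(values = values, cond = cond)
  }
  built <- if (is.null(seed)) build() else withr::with_seed(seed, build())

  structure(list(
    image = absorbance_image(built$values, pixel_um = pixel_um),
    nuclear_mask = nuclear,
    condensed_mask = built$cond,
    realized_fraction = if (n_nuc > 0) sum(built$cond) / n_nuc else NA_real_,
    params = list(condensed_fraction = condensed_fraction,
                  radius_um = radius_um, diffuse_level = diffuse_level,
                  condensed_level = condensed_level, noise_sd = noise_sd,
                  pixel_um = pixel_um, seed = seed)
  ), class = "nucleus_simulation")
}

#' Simulate an 8-bit 5mC immunofluorescence field
#'
#' Disk-shaped nuclei are placed without overlap on a uniform
#' background. The nuclear interior level is an affine increasing
#' function of the methylation level,
#' `40 + 180 * methylation_level` intensity units, so a fully
#' demethylated nucleus still stands clear of the default background.
#' Gaussian noise is added, then values are rounded and clipped to the
#' 8-bit range 0-255.
#'
#' @param n_nuclei Number of nuclei; 0 yields a background-only image.
#' @param methylation_level Real in `[0, 1]`.
#' @param background Background intensity, 0-255.
#' @param noise_sd Gaussian noise SD, intensity units.
#' @param seed Integer seed.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param radius_px Range of nuclear radii, pixels.
#' @param group,exposure Metadata labels; comparisons require matching
#'   exposure tags.
#' @return A `fluorescence_image` with ground-truth `masks`.
#' @export
generate_if_image <- function(n_nuclei, methylation_level,
                              background = 10, noise_sd = 5,
                              seed = NULL, dim = c(192L, 192L),
                              radius_px = c(12, 18),
                              group = NULL, exposure = "fixed") {
  if (methylation_level < 0 || methylation_level > 1) {
    stop("methylation_level must be in [0, 1]")
  }
  if (background < 0 || background > 255) stop("background must be in [0, 255]")
  level <- 40 + 180 * methylation_level
  if (background > 255 || level > 255) stop("signal not representable in 8 bits")
  nr <- dim[1L]; nc <- dim[2L]
  build <- function() {
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    values <- matrix(background, nr, nc)
    masks <- list()
    centers <- matrix(numeric(0), ncol = 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_nuclei && tries < 5000L) {
      r <- runif(1, radius_px[1L], radius_px[2L])
      ci <- runif(1, r + 1, nr - r)
      cj <- runif(1, r + 1, nc - r)
      if (nrow(centers) &&
          any(sqrt((centers[, 1] - ci)^2 + (centers[, 2] - cj)^2) <
              centers[, 3] + r + 2)) {
        tries <- tries + 1L; next
      }
      m <- (ys - ci)^2 + (xs - cj)^2 <= r^2
      values[m] <- level
      masks[[length(masks) + 1L]] <- m
      centers <- rbind(centers, c(ci, cj, r))
      placed <- placed + 1L
    }
    if (placed < n_nuclei) stop("could not place ", n_nuclei, " non-overlapping nuclei")
    if (noise_sd > 0) values <- values + rnorm(length(values), 0, noise_sd)
    values <- matrix(pmin(255, pmax(0, round(values))), nr, nc)
    list(values = values, masks = masks)
  }
  built <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  fluorescence_image(built$values, masks = built$masks,
                     meta = list(group = group, exposure = exposure,
                                 methylation_level = methylation_level,
                                 seed = seed))
}
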