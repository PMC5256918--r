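test_that("baseline correction zeroes a spectrum that is its own baseline", {
  wn <- full_grid()
  line <- 0.3 + 1e-4 * wn
  s <- spectrum(wn, line, state = "raw")
  out <- baseline_correct(s)
  expect_equal(out$absorbances, rep(0, length(wn)), tolerance = 1e-12)
  expect_equal(out$state, "baseline_corrected")
})

test_that("baseline correction is offset-invariant", {
  s <- generate_ftir_spectrum(0.8, baseline_coeffs = c(0.05, 5e-6),
                              noise_sd = 0.01, seed = 4)
  shifted <- spectrum(s$wavenumbers, s$absorbances + 0.37, state = "raw")
  expect_equal(baseline_correct(s)$absorbances,
               baseline_correct(shifted)$absorbances, tolerance = 1e-12)
})

test_that("baseline correction recovers a band over linear drift", {
  one <- list(band_spec(2500, 0.6, 40))
  s <- generate_ftir_spectrum(1, bands = one, baseline_coeffs = c(0.2, -3e-5))
  out <- baseline_correct(s)
  truth <- gaussian_profile(out$wavenumbers, 2500, 0.6, 40)
  # anchors sit in flat regions; tolerance covers interpolation residue
  expect_lt(max(abs(out$absorbances - truth)), 1e-3)
})

test_that("baseline correction demands raw input and in-range anchors", {
  s <- generate_ftir_spectrum(1)
  done <- baseline_correct(s)
  expect_error(baseline_correct(done), "raw")
  expect_error(baseline_correct(s, anchors = c(3600, 2700, 1800)), "4 anchor")
  expect_error(baseline_correct(s, anchors = c(3700, 2700, 1800, 800)), "range")
})

test_that("averaging is the pointwise mean with grid and state checks", {
  wn <- full_grid()
  a <- spectrum(wn, runif(701), state = "baseline_corrected")
  expect_equal(average_spectra(list(a))$absorbances, a$absorbances)

  minus <- spectrum(wn, -a$absorbances, state = "baseline_corrected")
  expect_equal(average_spectra(list(a, minus))$absorbances, rep(0, 701))

  raw <- spectrum(wn, runif(701), state = "raw")
  expect_error(average_spectra(list(a, raw)), "baseline-corrected")

  other <- spectrum(seq(3600, 804, by = -4), runif(700),
                    state = "baseline_corrected")
  expect_error(average_spectra(list(a, other)), "grid mismatch")
})

test_that("averaging 13 noisy replicates shrinks noise by sqrt(n)", {
  sigma <- 0.01
  reps <- lapply(1:13, function(i) {
    baseline_correct(generate_ftir_spectrum(0.6, noise_sd = sigma,
                                            seed = 700 + i))
  })
  avg <- average_spectra(reps)
  template <- average_spectra(list(
    baseline_correct(generate_ftir_spectrum(0.6, noise_sd = 0))))
  dev <- avg$absorbances - template$absorbances
  # baseline anchoring adds a small systematic part on top of noise
  expect_lt(stats::sd(dev), 3 * sigma / sqrt(13))
})

test_that("normalization sets the maximum to one and is idempotent", {
  s <- baseline_correct(generate_ftir_spectrum(0.9, noise_sd = 0.005, seed = 6))
  n1 <- normalize_max(s)
  expect_equal(max(n1$absorbances), 1, tolerance = 1e-15)
  n2 <- normalize_max(n1)
  expect_equal(n2$absorbances, n1$absorbances, tolerance = 1e-15)
  expect_equal(n1$state, "normalized")

  # the global maximum of a DNA-like spectrum is the NH/NH2 band
  wmax <- n1$wavenumbers[which.max(n1$absorbances)]
  expect_true(wmax <= 3425 && wmax >= 3395)

  flat0 <- spectrum(full_grid(), rep(0, 701), state = "baseline_corrected")
  expect_error(normalize_max(flat0), "degenerate")
  expect_error(normalize_max(generate_ftir_spectrum(1)), "corrected")
})

test_that("peak detection resolves the canonical shapes", {
  one <- gaussian_sum_spectrum(data.frame(center = 2930, height = 0.5, fwhm = 30))
  g <- detect_peaks(one, "low")
  expect_equal(nrow(g), 1)
  expect_lte(abs(g$center - 2930), 4)

  two <- gaussian_sum_spectrum(data.frame(center = c(2890, 2960),
                                          height = c(0.6, 0.5),
                                          fwhm = c(20, 20)))
  expect_equal(nrow(detect_peaks(two, "low")), 2)

  flat <- spectrum(seq(2992, 2852, by = -4), rep(0.2, 36),
                   state = "baseline_corrected")
  expect_equal(nrow(detect_peaks(flat, "low")), 0)

  short <- spectrum(seq(2992, 2972, by = -4), runif(6), state = "baseline_corrected")
  expect_error(detect_peaks(short), "8 points")
})

test_that("gaussian fit recovers a single known band and its closed-form area", {
  truth <- data.frame(center = 2935, height = 0.5, fwhm = 30)
  s <- gaussian_sum_spectrum(truth)
  fit <- fit_gaussian_peaks(s, detect_peaks(s, "low"))
  expect_equal(fit$n_peaks, 1)
  expect_equal(fit$peaks$center, 2935, tolerance = 1e-6)
  expect_equal(fit$peaks$height, 0.5, tolerance = 1e-6)
  expect_equal(fit$peaks$fwhm, 30, tolerance = 1e-6)
  expect_equal(fit$total_area, 0.5 * 30 * sqrt(pi / (4 * log(2))),
               tolerance = 1e-6)
  expect_equal(fit$total_area, 15.96, tolerance = 1e-3)
})

test_that("gaussian fit matches the analytic area of a two-band sum", {
  truth <- data.frame(center = c(2900, 2960), height = c(0.7, 0.4),
                      fwhm = c(25, 18))
  s <- gaussian_sum_spectrum(truth)
  fit <- fit_gaussian_peaks(s, detect_peaks(s, "high"))
  expect_equal(fit$n_peaks, 2)
  expect_equal(fit$total_area, sum(gaussian_area(truth$height, truth$fwhm)),
               tolerance = 1e-4)
})

test_that("fitted areas scale linearly with the absorbances", {
  truth <- data.frame(center = c(2910, 2965), height = c(0.8, 0.5),
                      fwhm = c(30, 15))
  s <- gaussian_sum_spectrum(truth)
  half <- spectrum(s$wavenumbers, s$absorbances * 0.5,
                   state = "baseline_corrected")
  f1 <- fit_gaussian_peaks(s, detect_peaks(s, "high"))
  f2 <- fit_gaussian_peaks(half, detect_peaks(half, "high"))
  expect_equal(f2$total_area, f1$total_area * 0.5, tolerance = 1e-6)
  expect_equal(sort(f2$peaks$area), sort(f1$peaks$area) * 0.5, tolerance = 1e-6)
})

test_that("band statistics table mirrors group ordering of methylation", {
  fits <- lapply(setNames(c(1.0, 0.6, 0.3), c("control", "vpa_1mM", "vpa_20mM")),
                 function(m) {
                   s <- simulate_group_spectrum(m, n_rep = 6,
                                                seed_base = round(m * 1e4))
                   fit_ch3_window(s)
                 })
  tab <- band_statistics_table(fits)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("group", "n_peaks", "main_peak_frequency",
                      "main_peak_area", "total_area"))
  expect_true(all(diff(tab$total_area) < 0))  # control > 1 mM > 20 mM

  one <- band_statistics_table(fits["control"])
  expect_equal(nrow(one), 1)
  expect_error(band_statistics_table(list()), "no fit results")
})

test_that("bend/cytosine absorbance ratio reads nearest-grid absorbances", {
  flat <- spectrum(full_grid(), rep(0.7, 701), state = "normalized")
  expect_equal(bend_cytosine_ratio(flat), 1.0)

  # 1375 band at twice the 1492 band height, negligible overlap
  bands <- list(band_spec(1375, 0.6, 20), band_spec(1492, 0.3, 20))
  s <- generate_ftir_spectrum(1, bands = bands)
  s$state <- "baseline_corrected"
  expect_equal(bend_cytosine_ratio(s), 2.0, tolerance = 0.05)

  # direction is parameterizable
  expect_equal(bend_cytosine_ratio(s, numerator = 1492, denominator = 1375),
               1 / bend_cytosine_ratio(s), tolerance = 1e-12)

  zero <- spectrum(full_grid(), c(rep(1, 700), 0), state = "normalized")
  zero$absorbances[zero$wavenumbers == 1492] <- 0
  expect_error(bend_cytosine_ratio(zero), "denominator")
})

test_that("qc report flags B-form, 1707 shoulder and phosphate ordering", {
  s <- simulate_group_spectrum(1.0, n_rep = 3, seed_base = 900)
  q <- qc_report(s)
  expect_true(q$bform_marker_present)
  expect_true(q$shoulder_1707_present)
  expect_true(q$ps_below_pas)
  expect_lt(q$ps_po2_absorbance, q$pas_po2_absorbance)

  # ablating the 1225 band removes the B-form marker
  lib <- Filter(function(b) b$center != 1225, default_dna_band_library())
  s2 <- generate_ftir_spectrum(1, bands = lib)
  s2$state <- "baseline_corrected"
  expect_false(qc_report(s2)$bform_marker_present)

  flat <- spectrum(full_grid(), rep(0.5, 701), state = "baseline_corrected")
  qf <- qc_report(flat)
  expect_false(qf$bform_marker_present)
  expect_false(qf$shoulder_1707_present)
  expect_false(qf$ps_below_pas)
})

test_that("band assignment lookup covers the shipped windows", {
  expect_match(assign_band(2935), "C-H stretching")
  expect_match(assign_band(1661), "thymine/adenine")
  expect_match(assign_band(3410), "NH")
  expect_match(assign_band(1228), "B-form")
  expect_equal(assign_band(900), "unassigned")
  expect_error(assign_band(500), "outside")
})
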