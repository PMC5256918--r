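test_that("default band library has the expected DNA band structure", {
  lib <- default_dna_band_library()
  centers <- vapply(lib, `[[`, numeric(1), "center")
  heights <- vapply(lib, `[[`, numeric(1), "height")
  scaled <- vapply(lib, `[[`, logical(1), "methylation_scaled")

  expect_true(all(centers >= 800 & centers <= 3600))
  expect_true(2935 %in% centers)
  expect_true(scaled[centers == 2935])
  expect_true(scaled[centers == 1375])
  # symmetric phosphate band sits below the antisymmetric one
  expect_lt(heights[centers == 1080], heights[centers == 1225])
  # NH/NH2 band is the global maximum of a noiseless library spectrum
  s <- generate_ftir_spectrum(1.0, bands = lib)
  wmax <- s$wavenumbers[which.max(s$absorbances)]
  expect_true(wmax <= 3425 && wmax >= 3395)
})

test_that("band_spec validates its arguments", {
  expect_error(band_spec(700, 1, 10), "outside")
  expect_error(band_spec(1500, 0, 10), "height")
  expect_error(band_spec(1500, 1, -2), "fwhm")
})

test_that("spectrum generator places single bands and scales flagged bands", {
  one <- list(band_spec(2000, 0.8, 30))
  s <- generate_ftir_spectrum(1.0, bands = one)
  expect_equal(s$wavenumbers[which.max(s$absorbances)], 2000)

  # methylation 0 removes exactly the flagged contribution
  s0 <- generate_ftir_spectrum(0, seed = 1)
  s1 <- generate_ftir_spectrum(1, seed = 1)
  at2935_0 <- absorbance_at(s0, 2935)
  at2935_1 <- absorbance_at(s1, 2935)
  expect_lt(at2935_0, 0.01)       # only far tails of unflagged bands remain
  expect_gt(at2935_1 - at2935_0, 0.3)

  expect_error(generate_ftir_spectrum(1, bands = list()), "no bands")
})

test_that("spectrum generator is deterministic under a fixed seed", {
  a <- generate_ftir_spectrum(0.5, noise_sd = 0.02, seed = 42)
  b <- generate_ftir_spectrum(0.5, noise_sd = 0.02, seed = 42)
  expect_identical(a$absorbances, b$absorbances)
  c <- generate_ftir_spectrum(0.5, noise_sd = 0.02, seed = 43)
  expect_false(identical(a$absorbances, c$absorbances))
})

test_that("CH3 window integral increases with methylation level", {
  integral <- vapply(seq(0, 1, by = 0.2), function(m) {
    s <- generate_ftir_spectrum(m)
    keep <- s$wavenumbers <= 2992 & s$wavenumbers >= 2850
    sum(s$absorbances[keep])
  }, numeric(1))
  expect_true(all(diff(integral) > 0))
})

test_that("nuclear map generator hits the requested condensed fraction", {
  # degenerate fractions
  s0 <- generate_nuclear_absorbance_map(0, seed = 1)
  expect_false(any(s0$condensed_mask))
  expect_equal(unique(s0$image$values[s0$nuclear_mask]), 0.06)

  s1 <- generate_nuclear_absorbance_map(1, seed = 1)
  expect_identical(s1$condensed_mask, s1$nuclear_mask)

  # mid fractions: realized fraction within one pixel of the request
  for (f in c(0.1, 0.4, 0.63, 0.9)) {
    sim <- generate_nuclear_absorbance_map(f, radius_um = 10, seed = round(100 * f))
    n_nuc <- sum(sim$nuclear_mask)
    expect_lte(abs(sim$realized_fraction - f), 1 / n_nuc + 1e-12)
    expect_true(all(sim$condensed_mask[sim$nuclear_mask] | TRUE)) # masks nest
    expect_true(all(!sim$condensed_mask[!sim$nuclear_mask]))
  }

  expect_error(generate_nuclear_absorbance_map(1.2), "condensed_fraction")
  expect_error(generate_nuclear_absorbance_map(0.5, condensed_level = 0.09),
               "recoverable")
})

test_that("nuclear map generator is deterministic and noise is truncated", {
  a <- generate_nuclear_absorbance_map(0.4, noise_sd = 0.02, seed = 7)
  b <- generate_nuclear_absorbance_map(0.4, noise_sd = 0.02, seed = 7)
  expect_identical(a$image$values, b$image$values)
  expect_true(all(a$image$values >= 0))
})

test_that("IF image generator produces ordered, clipped, seeded images", {
  lo <- generate_if_image(4, 0, noise_sd = 0, seed = 5)
  hi <- generate_if_image(4, 1, noise_sd = 0, seed = 5)
  expect_lt(mean(mean_nuclear_intensity(lo, background_correct = FALSE)),
            mean(mean_nuclear_intensity(hi, background_correct = FALSE)))
  expect_true(all(hi$values >= 0 & hi$values <= 255))

  a <- generate_if_image(6, 0.5, noise_sd = 8, seed = 11)
  b <- generate_if_image(6, 0.5, noise_sd = 8, seed = 11)
  expect_identical(a$values, b$values)

  empty <- generate_if_image(0, 0.5, noise_sd = 0, seed = 1)
  expect_length(empty$masks, 0)
  expect_equal(unique(as.vector(empty$values)), 10)
})
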