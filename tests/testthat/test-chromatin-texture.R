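test_that("nuclear mask applies the strict removal floor", {
  at_floor <- absorbance_image(matrix(0.020, 3, 3))
  expect_error(nuclear_mask(at_floor), "no nuclear signal")

  above <- absorbance_image(matrix(0.021, 3, 3))
  expect_true(all(nuclear_mask(above)))

  four <- absorbance_image(matrix(c(0.01, 0.05, 0.15, 0.25), 2))
  expect_equal(sum(nuclear_mask(four)), 3)
})

test_that("condensed mask applies an inclusive cutoff", {
  low <- absorbance_image(matrix(0.05, 2, 2))
  expect_equal(sum(condensed_mask(low)), 0)

  high <- absorbance_image(matrix(0.20, 2, 2))
  expect_identical(condensed_mask(high), nuclear_mask(high))

  mixed <- absorbance_image(matrix(c(0.05, 0.08, 0.15, 0.25), 2))
  expect_equal(sum(condensed_mask(mixed)), 2)

  # the cutoff value itself counts as condensed
  boundary <- absorbance_image(matrix(c(0.100, 0.05, 0.05, 0.05), 2))
  expect_equal(sum(condensed_mask(boundary)), 1)
})

test_that("measure_nucleus reproduces the worked 4-pixel example", {
  img <- absorbance_image(matrix(c(0.05, 0.08, 0.15, 0.25), 2), pixel_um = 0.5)
  m <- measure_nucleus(img)
  expect_equal(m$S_T, 1.0)
  expect_equal(m$S_C, 0.5)
  expect_equal(m$A_T, 0.53)
  expect_equal(m$A_C, 0.40)
  expect_equal(m$Sc_percent, 50.0)
  expect_equal(m$AAR, (0.40 / 0.5) / (0.53 / 1.0))
  expect_equal(round(m$AAR, 4), 1.5094)
})

test_that("measure_nucleus handles the degenerate texture cases", {
  uniform <- absorbance_image(matrix(0.2, 5, 5))
  m <- measure_nucleus(uniform)
  expect_equal(m$Sc_percent, 100)
  expect_equal(m$AAR, 1.0)

  decondensed <- absorbance_image(matrix(0.06, 4, 4))
  m2 <- measure_nucleus(decondensed)
  expect_equal(m2$Sc_percent, 0)
  expect_true(is.na(m2$AAR))
})

test_that("AAR is at least 1 for any measurable nucleus", {
  for (seed in 1:25) {
    vals <- withr::with_seed(seed, matrix(runif(100, 0, 0.4), 10))
    img <- absorbance_image(vals)
    m <- tryCatch(measure_nucleus(img), error = function(e) NULL)
    if (!is.null(m) && !is.na(m$AAR)) expect_gte(m$AAR, 1)
  }
})

test_that("texture statistics recover simulated ground truth exactly", {
  for (seed in c(3, 17, 52)) {
    f <- withr::with_seed(seed, runif(1, 0.1, 0.9))
    sim <- generate_nuclear_absorbance_map(f, radius_um = 9, seed = seed)
    m <- measure_nucleus(sim$image)
    fr <- sim$realized_fraction
    expect_equal(m$Sc_percent, 100 * fr)
    analytic <- sim$params$condensed_level /
      (fr * sim$params$condensed_level + (1 - fr) * sim$params$diffuse_level)
    expect_equal(m$AAR, analytic, tolerance = 1e-12)
  }
})

test_that("AAR increases with condensed-chromatin contrast at fixed masks", {
  sim <- generate_nuclear_absorbance_map(0.4, radius_um = 8, seed = 2)
  aar <- vapply(c(0.15, 0.25, 0.35), function(level) {
    v <- sim$image$values
    v[sim$condensed_mask] <- level
    measure_nucleus(absorbance_image(v))$AAR
  }, numeric(1))
  expect_true(all(diff(aar) > 0))
})

test_that("decondensation shifts the scatter: lower S_C%, higher AAR", {
  control <- generate_nuclear_absorbance_map(0.45, condensed_level = 0.22,
                                             diffuse_level = 0.06, seed = 31)
  treated <- generate_nuclear_absorbance_map(0.25, condensed_level = 0.30,
                                             diffuse_level = 0.05, seed = 32)
  mc <- measure_nucleus(control$image)
  mt <- measure_nucleus(treated$image)
  expect_lt(mt$Sc_percent, mc$Sc_percent)
  expect_gt(mt$AAR, mc$AAR)
})

test_that("batch measurement labels rows and tolerates bad images", {
  sims <- lapply(1:5, function(i) generate_nuclear_absorbance_map(0.3, seed = i))
  tab <- batch_measure(sims, group_label = "control")
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$group == "control"))
  expect_named(tab, c("id", "group", "S_T_um2", "S_C_um2", "A_T", "A_C",
                      "Sc_percent", "AAR"))

  expect_error(batch_measure(list(), "x"), "no images")

  blank <- absorbance_image(matrix(0.01, 4, 4))
  expect_warning(
    tab2 <- batch_measure(c(sims[1:2], list(bad = blank)), "g"),
    "failed")
  expect_equal(nrow(tab2), 2)
  expect_length(attr(tab2, "failures"), 1)
})

test_that("absorbance images round-trip through CSV and TIFF", {
  sim <- generate_nuclear_absorbance_map(0.4, seed = 9)
  for (ext in c("csv", "tif")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_absorbance_image(sim$image, path)
    back <- read_absorbance_image(path)
    expect_equal(back$values, sim$image$values, tolerance = 1e-6)
  }
})
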