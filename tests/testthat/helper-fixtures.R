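# Shared fixtures and independent oracles.

# Standard descending acquisition grid, 3600 -> 800 cm^-1 at 4 cm^-1.
full_grid <- function() seq(3600, 800, by = -4)

# Spectrum that is an exact sum of Gaussians on a window grid.
gaussian_sum_spectrum <- function(truth, hi = 2992, lo = 2852, step = 4,
                                  state = "baseline_corrected") {
  wn <- seq(hi, lo, by = -step)
  y <- rep(0, length(wn))
  for (i in seq_len(nrow(truth))) {
    y <- y + gaussian_profile(wn, truth$center[i], truth$height[i], truth$fwhm[i])
  }
  spectrum(wn, y, state = state)
}

# Well-separated random 1-3 Gaussian configurations: centers >= 35 cm^-1
# apart, FWHM 12-25 cm^-1, heights 0.3-1 — identifiable deconvolution
# cases for the fit oracle.
draw_gaussian_truth <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(1:3, 1)
    repeat {
      centers <- sort(runif(k, 2870, 2975))
      if (k == 1 || min(diff(centers)) >= 35) break
    }
    data.frame(center = centers,
               height = runif(k, 0.3, 1),
               fwhm = runif(k, 12, 25))
  })
}

# Exhaustive-permutation Mann-Whitney oracle: enumerate every
# assignment of the pooled values to the two groups, build the exact
# null distribution of U, and take the two-sided tail probability.
# Independent of wilcox.test.
permutation_mw_p <- function(x, y) {
  z <- c(x, y)
  n_a <- length(x)
  r <- rank(z)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(z), n_a)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Full FT-IR chain for one synthetic group: replicates -> baseline ->
# average -> normalize. Returns the normalized spectrum.
simulate_group_spectrum <- function(methylation_level, n_rep, seed_base,
                                    noise_sd = 0.01,
                                    baseline_coeffs = c(0.05, 5e-6)) {
  reps <- lapply(seq_len(n_rep), function(i) {
    baseline_correct(generate_ftir_spectrum(
      methylation_level,
      baseline_coeffs = baseline_coeffs,
      noise_sd = noise_sd,
      seed = seed_base + i))
  })
  normalize_max(average_spectra(reps))
}
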