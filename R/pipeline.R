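# End-to-end runner: executes any combination of the three assay arms
# from a single config (list or YAML file), writes per-arm tables plus
# a combined JSON report, and logs seeds/parameters so a run can be
# reproduced exactly.

#' Demo pipeline configuration
#'
#' All-synthetic three-group study: a control and two treatment doses
#' with methylation levels 1.0 / 0.6 / 0.3 (illustrative defaults for a
#' demethylating dose series). The cytometry arm simulates 50 nuclei
#' per group; the FT-IR arm simulates 6 / 13 / 9 replicate spectra; the
#' IF arm simulates 3 fields of 8 nuclei per group at noise SD 10.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer master seed.
#' @return Config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir, seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cytometry = list(
      groups = list(
        control = list(n = 50, condensed_fraction = 0.45,
                       diffuse_level = 0.06, condensed_level = 0.22,
                       noise_sd = 0.005),
        vpa_1mM = list(n = 50, condensed_fraction = 0.30,
                       diffuse_level = 0.05, condensed_level = 0.28,
                       noise_sd = 0.005)
      ),
      pairs = list(c("control", "vpa_1mM"))
    ),
    ftir = list(
      groups = list(
        control = list(n = 6, methylation_level = 1.0),
        vpa_1mM = list(n = 13, methylation_level = 0.6),
        vpa_20mM = list(n = 9, methylation_level = 0.3)
      ),
      noise_sd = 0.01,
      baseline_coeffs = c(0.05, 5e-6),
      window = c(2992, 2850),
      sensitivity = "low"
    ),
    ifquant = list(
      groups = list(
        control = list(n_images = 3, n_nuclei = 8, methylation_level = 1.0),
        vpa_1mM = list(n_images = 3, n_nuclei = 8, methylation_level = 0.6),
        vpa_20mM = list(n_images = 3, n_nuclei = 8, methylation_level = 0.3)
      ),
      noise_sd = 10,
      pairs = list(c("control", "vpa_1mM"), c("control", "vpa_20mM"),
                   c("vpa_1mM", "vpa_20mM"))
    )
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# per-arm seed streams derived from the master seed; offsets keep the
# derived seeds distinct and below 2^31
arm_seed <- function(seed, arm, i = 0L) {
  (as.integer(seed) * 1009L + match(arm, c("cytometry", "ftir", "ifquant")) * 131071L +
     as.integer(i)) %% .Machine$integer.max
}

run_cytometry_arm <- function(cfg, seed, out_dir) {
  tables <- list()
  for (g in names(cfg$groups)) {
    gc <- cfg$groups[[g]]
    sims <- lapply(seq_len(gc$n), function(i) {
      generate_nuclear_absorbance_map(
        condensed_fraction = gc$condensed_fraction,
        diffuse_level = gc$diffuse_level %||% 0.06,
        condensed_level = gc$condensed_level %||% 0.25,
        noise_sd = gc$noise_sd %||% 0,
        seed = arm_seed(seed, "cytometry",
                        i + 10000L * match(g, names(cfg$groups))))
    })
    tables[[g]] <- batch_measure(sims, group_label = g)
  }
  measurements <- do.call(rbind, tables)
  rownames(measurements) <- NULL
  write_tsv(measurements, file.path(out_dir, "cytometry.tsv"))
  comparisons <- NULL
  if (length(cfg$pairs %||% list())) {
    comparisons <- rbind(
      compare_conditions(measurements, "Sc_percent", cfg$pairs),
      compare_conditions(measurements, "AAR", cfg$pairs)
    )
    write_tsv(comparisons, file.path(out_dir, "cytometry_comparisons.tsv"))
  }
  p <- plot_texture_scatter(measurements)
  grDevices::png(file.path(out_dir, "cytometry_scatter.png"),
                 width = 900, height = 700, res = 150)
  print(p)
  grDevices::dev.off()
  list(measurements = measurements, comparisons = comparisons)
}

run_ftir_arm <- function(cfg, seed, out_dir) {
  window <- cfg$window %||% c(2992, 2850)
  fits <- list()
  ratios <- list()
  qc <- list()
  for (g in names(cfg$groups)) {
    gc <- cfg$groups[[g]]
    reps <- lapply(seq_len(gc$n), function(i) {
      s <- generate_ftir_spectrum(
        methylation_level = gc$methylation_level,
        baseline_coeffs = cfg$baseline_coeffs %||% 0,
        noise_sd = cfg$noise_sd %||% 0,
        seed = arm_seed(seed, "ftir", i + 10000L * match(g, names(cfg$groups))),
        meta = list(group = g, replicate = i))
      baseline_correct(s)
    })
    avg <- average_spectra(reps)
    norm <- normalize_max(avg)
    fits[[g]] <- fit_ch3_window(norm, hi = max(window), lo = min(window),
                                sensitivity = cfg$sensitivity %||% "low")
    ratios[[g]] <- bend_cytosine_ratio(norm)
    q <- qc_report(norm)
    qc[[g]] <- unclass(q)
    write_spectrum(norm, file.path(out_dir, paste0("ftir_normalized_", g, ".csv")))
  }
  summary <- band_statistics_table(fits)
  write_tsv(summary, file.path(out_dir, "ftir_summary.tsv"))
  ratio_df <- data.frame(group = names(ratios),
                         ratio_1375_1492 = unlist(ratios),
                         stringsAsFactors = FALSE)
  rownames(ratio_df) <- NULL
  write_tsv(ratio_df, file.path(out_dir, "ftir_ratios.tsv"))
  jsonlite::write_json(qc, file.path(out_dir, "ftir_qc.json"),
                       auto_unbox = TRUE, digits = NA)
  list(summary = summary, ratios = ratio_df, qc = qc, fits = fits)
}

run_ifquant_arm <- function(cfg, seed, out_dir) {
  images <- list()
  labels <- character(0)
  for (g in names(cfg$groups)) {
    gc <- cfg$groups[[g]]
    for (i in seq_len(gc$n_images)) {
      images[[paste0(g, "_", i)]] <- generate_if_image(
        n_nuclei = gc$n_nuclei, methylation_level = gc$methylation_level,
        noise_sd = cfg$noise_sd %||% 5,
        seed = arm_seed(seed, "ifquant", i + 10000L * match(g, names(cfg$groups))),
        group = g)
      labels <- c(labels, g)
    }
  }
  table <- if_measure_batch(images, labels)
  write_tsv(table, file.path(out_dir, "if_intensities.tsv"))
  comparisons <- NULL
  if (length(cfg$pairs %||% list())) {
    comparisons <- compare_conditions(table, "mean_intensity", cfg$pairs)
    write_tsv(comparisons, file.path(out_dir, "if_comparisons.tsv"))
  }
  surface <- intensity_surface(images[[1L]], factor = cfg$surface_factor %||% 4L)
  utils::write.csv(surface, file.path(out_dir, "if_surface.csv"), row.names = FALSE)
  list(measurements = table, comparisons = comparisons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline from a config
#'
#' Executes the requested arms (`cytometry`, `ftir`, `ifquant`) end to
#' end — simulation, measurement, statistics — and writes a report
#' bundle (TSV tables, normalized spectra, QC JSON, a scatter plot and
#' a combined `report.json` recording package version, seed and
#' parameters). A config with no arms is an error; a failing arm is
#' reported in the bundle and the returned `status`, without aborting
#' the other arms.
#'
#' @param config Config list (see [demo_config()]) or path to a YAML
#'   file with the same structure.
#' @return Invisibly, a list with per-arm results, `status`
#'   (`"ok"`/`"failed"` per arm) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  arms <- intersect(c("cytometry", "ftir", "ifquant"), names(config))
  if (!length(arms)) stop("nothing to do: config names no analysis arms")
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  status <- list()
  for (arm in arms) {
    res <- tryCatch(
      switch(arm,
             cytometry = run_cytometry_arm(config$cytometry, seed, out_dir),
             ftir = run_ftir_arm(config$ftir, seed, out_dir),
             ifquant = run_ifquant_arm(config$ifquant, seed, out_dir)),
      error = function(e) e)
    if (inherits(res, "error")) {
      status[[arm]] <- paste0("failed: ", conditionMessage(res))
    } else {
      results[[arm]] <- res
      status[[arm]] <- "ok"
    }
  }
  report <- list(
    package = "methylscope",
    version = as.character(utils::packageVersion("methylscope")),
    seed = seed,
    arms = status,
    config = config[setdiff(names(config), "out_dir")]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (any(unlist(status) != "ok")) {
    warning("pipeline arm(s) failed: ",
            paste(names(status)[unlist(status) != "ok"], collapse = ", "))
  }
  invisible(list(results = results, status = status, out_dir = out_dir))
}
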