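#' Default wavenumber-standard band list
#'
#' Band positions (cm^-1) used to synthesize and calibrate the
#' wavenumber-standard frames, following common instrument convention for
#' an acetaminophen-type standard in the fingerprint region.
#'
#' @return Numeric vector of band positions, cm^-1.
#' @export
default_known_bands <- function() {
  c(465.1, 651.6, 857.9, 1168.5, 1323.9, 1648.4)
}

#' Preprocess a reference library like the measurements
#'
#' Truncates the reference signatures to the retained channel range and
#' applies SNV, so references and measurements live in the same space.
#'
#' @param refs a [reference_library()] on the raw channel axis.
#' @param n_drop leading channels to drop.
#' @return A [reference_library()] of SNV-normalized signatures.
#' @export
process_reference_library <- function(refs, n_drop = 0L) {
  cut <- function(sp) {
    keep <- if (n_drop > 0) -seq_len(n_drop) else seq_along(sp$wavenumber)
    snv(sors_spectrum(sp$wavenumber[keep], sp$intensity[keep]))
  }
  nm <- refs$roles
  reference_library(cut(ref_top(refs)), cut(ref_bottom(refs)),
                    names_ = c(nm[["top"]], nm[["bottom"]]))
}

#' Build a run configuration
#'
#' Collects every tunable of a simulated depth-sensing study. Two
#' profiles are provided: `"full"` mirrors the instrument-scale geometry
#' (40 offsets x 42 line positions x 1024 channels, 1e5 photons per
#' phantom) and `"micro"` keeps the same offset grid and processing chain
#' on reduced spatial/spectral sampling for fast exploratory runs.
#'
#' @param scale `"micro"` (default) or `"full"`.
#' @param seed integer root seed; every stage RNG stream derives from it.
#' @param phantom_table path to a CSV with columns `recipe`,
#'   `thickness_um`, `mu_a_cm`, `mu_s_prime_cm` (defaults to the table
#'   shipped with the package).
#' @param out_dir output directory or NULL.
#' @param ... named overrides merged into the configuration
#'   (`acquisition`, `noise`, `bottom`, `n_photons`, `preprocess`,
#'   `analysis`, `calibration`).
#' @return A `run_config` list.
#' @export
run_config <- function(scale = c("micro", "full"), seed = 1L,
                       phantom_table = NULL, out_dir = NULL, ...) {
  scale <- match.arg(scale)
  if (is.null(phantom_table)) {
    phantom_table <- system.file("extdata", "phantom_table.csv",
                                 package = "sorsdepth")
  }
  base <- if (scale == "full") {
    list(acquisition = list(offset_start = 0, offset_step = 0.25,
                            n_offsets = 40L, n_line_positions = 42L,
                            n_channels = 1024L, exposure_scale = 1e5,
                            n_filter_channels = 120L),
         n_photons = 1e5,
         preprocess = list(min_bubble_width = 75L))
  } else {
    list(acquisition = list(offset_start = 0, offset_step = 0.25,
                            n_offsets = 40L, n_line_positions = 4L,
                            n_channels = 192L, exposure_scale = 1e5,
                            n_filter_channels = 0L),
         n_photons = 1500,
         preprocess = list(min_bubble_width = 45L))
  }
  cfg <- modifyList(list(
    scale = scale,
    seed = as.integer(seed),
    phantom_table = phantom_table,
    out_dir = out_dir,
    acquisition = base$acquisition,
    noise = list(shot_noise_enabled = TRUE, read_noise_sd = 2,
                 cosmic_rate = 0.2, cosmic_amplitude_range = c(1e3, 2e4),
                 smile_coefficients = c(0, 0, 0.002),
                 baseline_amplitude = 2),
    bottom = c(mu_a = 0.1, mu_s_prime = 5),
    n_photons = base$n_photons,
    preprocess = modifyList(list(z_threshold = 8, window = 5L,
                                 despike = TRUE, baseline = TRUE),
                            base$preprocess),
    analysis = list(aggregate = "mean_sam", smooth_window = 5L),
    calibration = list(enabled = TRUE,
                       known_bands = default_known_bands(),
                       degree = 3L)
  ), list(...))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  scale <- y$scale %||% "micro"
  seed <- y$seed %||% 1L
  y$scale <- NULL; y$seed <- NULL
  do.call(run_config, c(list(scale = scale, seed = seed), y))
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$phantom_table)) {
    stop("phantom table not found: ", config$phantom_table)
  }
  invisible(config)
}

# Deterministic 31-bit polynomial hash of the serialized configuration,
# recorded for provenance (not cryptographic).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

phantom_seed <- function(root_seed, k) {
  as.integer((as.numeric(root_seed) + 7919 * k) %% 2147483629)
}

# Shared machinery: simulate, preprocess and analyze one phantom.
analyze_phantom <- function(phantom, acq, noise, refs_raw, refs_proc, cal,
                            preprocess_params, analysis, bottom, n_photons,
                            seed) {
  fractions <- sample_photon_paths(phantom, acq, n_photons, seed,
                                   bottom = bottom)
  cube <- simulate_cube(phantom, refs_raw, acq, noise, fractions)
  proc <- preprocess_cube(cube, cal, preprocess_params)
  curve <- sam_curve(proc, refs_proc, aggregate = analysis$aggregate)
  co <- find_crossover(curve)
  co$plateau_offset <- find_detectability_limit(curve, analysis$smooth_window)
  list(fractions = fractions, cube = proc, curve = curve, crossover = co)
}

build_study_calibration <- function(config, acq, noise, true_axis) {
  pre <- config$preprocess
  n_drop <- acq$n_filter_channels
  if (!isTRUE(config$calibration$enabled)) {
    return(list(cal = calibration_set(),
                pre = modifyList(pre, list(n_drop = n_drop))))
  }
  a <- true_axis$coefficients
  known <- config$calibration$known_bands
  known <- known[known > min(true_axis$wavenumber) + 20 &
                   known < max(true_axis$wavenumber) - 20]
  band_px <- (known - a[1]) / a[2]
  frames <- make_calibration_frames(acq, band_px,
                                    smile_coefficients = noise$smile_coefficients,
                                    noise = NULL)
  px_keep <- (seq_len(acq$n_channels) - 1)[if (n_drop > 0) -seq_len(n_drop) else TRUE]
  certified <- 0.4 + 0.6 * exp(-((px_keep - 0.55 * acq$n_channels) /
                                   (0.35 * acq$n_channels))^2)
  cal <- build_calibration_set(frames$wavenumber_frame, frames$response_frame,
                               known_bands = known, certified_curve = certified,
                               n_drop = n_drop,
                               degree = min(config$calibration$degree,
                                            length(known) - 1))
  list(cal = cal, pre = modifyList(pre, list(n_drop = n_drop)))
}

#' Run the bilayer phantom depth-sensing study
#'
#' For every phantom in the configured table: photon-transport Monte
#' Carlo, cube simulation, preprocessing, SAM curves, crossover and
#' plateau detection; then one power-law depth model per optical-property
#' recipe. Deterministic given (configuration, seed).
#'
#' @param config a [run_config()].
#' @return A `run_report`: list with `phantoms` (one row per phantom),
#'   `models` (one row per fittable recipe), `unfittable`, `seed`,
#'   `config_hash`, `n_offsets`.
#' @export
run_phantom_study <- function(config = run_config()) {
  validate_run_config(config)
  tab <- read.csv(config$phantom_table)
  acq <- do.call(acquisition_config, config$acquisition)
  true_axis <- simulated_pixel_axis(acq$n_channels, acq$n_filter_channels)
  refs_raw <- default_reference_library(true_axis$wavenumber)
  stage <- build_study_calibration(config, acq,
                                   do.call(noise_config,
                                           c(config$noise, rng_seed = 1L)),
                                   true_axis)
  refs_proc <- process_reference_library(refs_raw, acq$n_filter_channels)

  rows <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    seed_k <- phantom_seed(config$seed, k)
    phantom <- phantom_spec(tab$recipe[k], tab$thickness_um[k] / 1000,
                            tab$mu_a_cm[k], tab$mu_s_prime_cm[k])
    noise_k <- do.call(noise_config, c(config$noise, rng_seed = seed_k))
    res <- tryCatch(
      withCallingHandlers(
        analyze_phantom(phantom, acq, noise_k, refs_raw, refs_proc,
                        stage$cal, stage$pre, config$analysis,
                        config$bottom, config$n_photons, seed_k),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) {
        stop(sprintf("phantom %s (t=%g um) failed: %s",
                     tab$recipe[k], tab$thickness_um[k], conditionMessage(e)))
      })
    rows[[k]] <- data.frame(recipe = tab$recipe[k],
                            thickness_um = tab$thickness_um[k],
                            mu_a = tab$mu_a_cm[k],
                            mu_s_prime = tab$mu_s_prime_cm[k],
                            delta_s_co = res$crossover$delta_s_co,
                            status = res$crossover$status,
                            plateau_offset = res$crossover$plateau_offset)
  }
  phantoms <- do.call(rbind, rows)
  curves <- build_depth_curves(
    data.frame(recipe = phantoms$recipe, mu_a = phantoms$mu_a,
               mu_s_prime = phantoms$mu_s_prime,
               thickness_um = phantoms$thickness_um,
               delta_s_co = phantoms$delta_s_co,
               status = phantoms$status))
  models <- if (length(curves$models)) {
    do.call(rbind, lapply(names(curves$models), function(nm) {
      m <- curves$models[[nm]]
      data.frame(recipe = nm, mu_a = m$optical_properties[1],
                 mu_s_prime = m$optical_properties[2],
                 A = m$A, phi = m$phi, residual_norm = m$residual_norm)
    }))
  } else {
    data.frame(recipe = character(), mu_a = numeric(),
               mu_s_prime = numeric(), A = numeric(), phi = numeric(),
               residual_norm = numeric())
  }
  report <- list(phantoms = phantoms, models = models,
                 unfittable = curves$unfittable,
                 seed = config$seed, config_hash = config_hash(config),
                 n_offsets = acq$n_offsets)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Run the bilayer tissue proof-of-concept analog
#'
#' Simulates a strongly scattering fat-substitute top layer (defaults
#' mu_a = 0.03 cm^-1, mu_s_prime = 200 cm^-1, the accepted estimate for a
#' 20% lipid emulsion at 785 nm) over a protein-rich bottom layer, for a
#' set of layer thicknesses, and reports the SAM curve and crossover
#' status per thickness.
#'
#' @param config a [run_config()].
#' @param thicknesses_mm top-layer thicknesses, mm (default 0.5, 1, 3).
#' @param top named vector with `mu_a`, `mu_s_prime` of the top layer,
#'   cm^-1.
#' @return List with `curves` (one `sam_curve` per thickness),
#'   `crossovers`, and a `summary` data frame.
#' @export
run_bilayer_poc <- function(config = run_config(),
                            thicknesses_mm = c(0.5, 1, 3),
                            top = c(mu_a = 0.03, mu_s_prime = 200)) {
  validate_run_config(config)
  acq <- do.call(acquisition_config, config$acquisition)
  true_axis <- simulated_pixel_axis(acq$n_channels, acq$n_filter_channels)
  refs_raw <- default_reference_library(true_axis$wavenumber)
  stage <- build_study_calibration(config, acq,
                                   do.call(noise_config,
                                           c(config$noise, rng_seed = 1L)),
                                   true_axis)
  refs_proc <- process_reference_library(refs_raw, acq$n_filter_channels)
  curves <- list(); crossovers <- list(); rows <- list()
  for (k in seq_along(thicknesses_mm)) {
    t_mm <- thicknesses_mm[k]
    seed_k <- phantom_seed(config$seed, 1000 + k)
    phantom <- phantom_spec(sprintf("poc_t%.1fmm", t_mm), t_mm,
                            top[["mu_a"]], top[["mu_s_prime"]])
    noise_k <- do.call(noise_config, c(config$noise, rng_seed = seed_k))
    res <- withCallingHandlers(
      analyze_phantom(phantom, acq, noise_k, refs_raw, refs_proc,
                      stage$cal, stage$pre, config$analysis,
                      config$bottom, config$n_photons, seed_k),
      warning = function(w) invokeRestart("muffleWarning"))
    curves[[k]] <- res$curve
    crossovers[[k]] <- res$crossover
    rows[[k]] <- data.frame(thickness_mm = t_mm,
                            delta_s_co = res$crossover$delta_s_co,
                            status = res$crossover$status)
  }
  list(curves = curves, crossovers = crossovers,
       summary = do.call(rbind, rows))
}

#' Write a run report to disk
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$phantoms, file.path(dir, "phantoms.csv"),
            row.names = FALSE)
  write.csv(report$models, file.path(dir, "depth_models.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(seed = report$seed,
                            config_hash = report$config_hash,
                            n_offsets = report$n_offsets,
                            unfittable = report$unfittable),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d phantoms, %d fitted recipes, %d unfittable (seed %d, config %s)\n",
              nrow(x$phantoms), nrow(x$models), length(x$unfittable),
              x$seed, x$config_hash))
  invisible(x)
}
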