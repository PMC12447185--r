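#' Describe a bilayer phantom
#'
#' A phantom is a finite top layer of thickness `thickness_t` with optical
#' properties (`mu_a`, `mu_s_prime`) over a semi-infinite bottom layer.
#' Coefficients are accepted in cm^-1 (the convention of tissue-optics
#' tables) and converted to mm^-1 internally; all lengths are mm.
#'
#' @param recipe_name label for the optical-property recipe.
#' @param thickness_t top-layer thickness, mm, >= 0.
#' @param mu_a absorption coefficient of the top layer, cm^-1.
#' @param mu_s_prime reduced scattering coefficient of the top layer, cm^-1.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(recipe_name, thickness_t, mu_a, mu_s_prime) {
  if (thickness_t < 0) stop("thickness_t must be >= 0")
  if (mu_a < 0 || mu_s_prime < 0) stop("optical coefficients must be >= 0")
  structure(list(recipe_name = as.character(recipe_name),
                 thickness_t = as.numeric(thickness_t),
                 mu_a = as.numeric(mu_a),
                 mu_s_prime = as.numeric(mu_s_prime)),
            class = "phantom_spec")
}

#' Acquisition geometry of a line-scanned SORS measurement
#'
#' Defaults reproduce the line-scanning protocol this package targets: the
#' detection line starts on the laser line and is stepped away in 0.25 mm
#' increments for 40 measurements, each frame holding 42 spectra of 1024
#' raw channels. Note that a 0.25 mm step over 40 measurements spans
#' offsets 0 to 9.75 mm; descriptions of the scan as covering "0 to 10 mm"
#' round this up.
#'
#' @param offset_start first spatial offset, mm.
#' @param offset_step offset increment, mm, > 0.
#' @param n_offsets number of detection-line positions, >= 2.
#' @param n_line_positions number of spatial pixels along the line.
#' @param n_channels number of raw spectral channels, >= 2.
#' @param exposure_scale photon-count scale factor applied to simulated
#'   clean spectra (controls the shot-noise regime).
#' @param n_filter_channels leading channels blocked by the long-pass
#'   filter (zero signal; truncated during preprocessing). Defaults to 120
#'   for full-size 1024-channel frames and 0 otherwise.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(offset_start = 0, offset_step = 0.25,
                               n_offsets = 40L, n_line_positions = 42L,
                               n_channels = 1024L, exposure_scale = 1e5,
                               n_filter_channels = NULL) {
  if (offset_step <= 0) stop("offset_step must be > 0")
  if (n_offsets < 2) stop("n_offsets must be >= 2")
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (is.null(n_filter_channels)) {
    n_filter_channels <- if (n_channels >= 1024L) 120L else 0L
  }
  if (n_filter_channels >= n_channels) stop("n_filter_channels >= n_channels")
  structure(list(offset_start = offset_start, offset_step = offset_step,
                 n_offsets = as.integer(n_offsets),
                 n_line_positions = as.integer(n_line_positions),
                 n_channels = as.integer(n_channels),
                 exposure_scale = exposure_scale,
                 n_filter_channels = as.integer(n_filter_channels)),
            class = "acquisition_config")
}

#' Offset grid of an acquisition
#' @param acq an [acquisition_config()].
#' @return Numeric vector of spatial offsets, mm.
#' @export
acq_offsets <- function(acq) {
  acq$offset_start + acq$offset_step * (seq_len(acq$n_offsets) - 1)
}

#' Instrument-artifact configuration for the simulator
#'
#' Parameterizes the artifacts injected on top of the clean mixture
#' spectra: Poisson shot noise, Gaussian read noise, single-channel cosmic
#' ray spikes, spectrometer smile (a polynomial channel shift across the
#' spatial rows) and a broad fluorescence baseline per material.
#'
#' @param shot_noise_enabled apply Poisson shot noise to photon counts.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param cosmic_rate expected cosmic spikes per frame (Poisson).
#' @param cosmic_amplitude_range length-2 range of spike amplitudes, counts.
#' @param smile_coefficients polynomial coefficients (increasing degree) of
#'   the per-row channel shift, evaluated at row index 0, 1, ...
#' @param baseline_amplitude fluorescence baseline height relative to unit
#'   reference-signature amplitude.
#' @param baseline_top,baseline_bottom `(center cm^-1, fwhm cm^-1)` of the
#'   broad Gaussian fluorescence shape of each material.
#' @param rng_seed integer root seed; identical seed and configuration give
#'   bit-identical cubes.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(shot_noise_enabled = TRUE, read_noise_sd = 2,
                         cosmic_rate = 0.2,
                         cosmic_amplitude_range = c(1e3, 2e4),
                         smile_coefficients = c(0, 0, 0.002),
                         baseline_amplitude = 2,
                         baseline_top = c(1250, 1600),
                         baseline_bottom = c(1450, 1800),
                         rng_seed = 1L) {
  if (read_noise_sd < 0 || cosmic_rate < 0 || baseline_amplitude < 0) {
    stop("rates and amplitudes must be >= 0")
  }
  if (any(cosmic_amplitude_range < 0) || diff(cosmic_amplitude_range) < 0) {
    stop("cosmic_amplitude_range must be a non-negative increasing range")
  }
  structure(list(shot_noise_enabled = isTRUE(shot_noise_enabled),
                 read_noise_sd = read_noise_sd,
                 cosmic_rate = cosmic_rate,
                 cosmic_amplitude_range = cosmic_amplitude_range,
                 smile_coefficients = smile_coefficients,
                 baseline_amplitude = baseline_amplitude,
                 baseline_top = baseline_top,
                 baseline_bottom = baseline_bottom,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_config")
}

#' Noise configuration with every artifact disabled
#' @param rng_seed integer root seed.
#' @return A [noise_config()] producing clean, baseline-free cubes.
#' @export
noise_config_off <- function(rng_seed = 1L) {
  noise_config(shot_noise_enabled = FALSE, read_noise_sd = 0,
               cosmic_rate = 0, cosmic_amplitude_range = c(0, 0),
               smile_coefficients = 0, baseline_amplitude = 0,
               rng_seed = rng_seed)
}

#' Raw pixel-to-wavenumber map used by the simulator
#'
#' Ground-truth linear map from raw channel index (0-based) to wavenumber.
#' It is laid out so that dropping the first `n_filter` channels leaves the
#' fingerprint region 400-2100 cm^-1, mirroring a long-pass filter cutoff
#' at the start of the sensor.
#'
#' @param n_channels raw channel count.
#' @param n_filter channels below the filter cutoff (default 120).
#' @return List with `wavenumber` (length `n_channels`) and the linear
#'   `coefficients` (intercept, slope per channel).
#' @export
simulated_pixel_axis <- function(n_channels = 1024L, n_filter = 120L) {
  slope <- (2100 - 400) / (n_channels - 1 - n_filter)
  intercept <- 400 - slope * n_filter
  px <- seq_len(n_channels) - 1
  list(wavenumber = intercept + slope * px,
       coefficients = c(intercept, slope))
}

#' Monte Carlo photon transport through a bilayer phantom
#'
#' Launches isotropic random-walk photons into the phantom and tabulates,
#' per spatial-offset bin, the detected Raman weight and the fraction of it
#' whose conversion site lies in the bottom layer. This is the forward
#' model linking spatial offset to sampling depth: photons detected at
#' larger lateral exit distance have, on average, visited deeper.
#'
#' @param phantom a [phantom_spec()].
#' @param acq an [acquisition_config()]; its offset grid defines the
#'   lateral detection bins (each offset +- half a step).
#' @param n_photons photons to launch, >= 1.
#' @param seed integer RNG seed.
#' @param bottom named list or vector with `mu_a` and `mu_s_prime` (cm^-1)
#'   of the semi-infinite bottom layer.
#' @param max_steps hard cap on scattering events per photon.
#' @param roulette_threshold,roulette_survival Russian-roulette parameters
#'   terminating low-weight photons without bias.
#' @return An `offset_fraction_table`: data frame with columns `offset`
#'   (mm), `fraction_bottom` (NA in empty bins), `total_weight` (detected
#'   weight per launched photon) and `n_detected`. Attribute `no_detected`
#'   is TRUE when no photon was detected anywhere.
#' @export
sample_photon_paths <- function(phantom, acq, n_photons, seed,
                                bottom = c(mu_a = 0.1, mu_s_prime = 5),
                                max_steps = 20000L,
                                roulette_threshold = 1e-4,
                                roulette_survival = 0.1) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(acq, "acquisition_config"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  offsets <- acq_offsets(acq)
  half <- acq$offset_step / 2
  edges <- c(pmax(0, offsets[1] - half), offsets + half)
  res <- with_local_seed(stage_seed(seed, "photon"), {
    cpp_photon_walk(phantom$thickness_t,
                    phantom$mu_a / 10, phantom$mu_s_prime / 10,
                    bottom[["mu_a"]] / 10, bottom[["mu_s_prime"]] / 10,
                    edges, as.integer(n_photons), as.integer(max_steps),
                    roulette_threshold, roulette_survival)
  })
  frac <- ifelse(res$w_total > 0, res$w_bottom / res$w_total, NA_real_)
  tab <- data.frame(offset = offsets,
                    fraction_bottom = frac,
                    total_weight = res$w_total / n_photons,
                    n_detected = res$n_detected)
  attr(tab, "n_photons") <- as.integer(n_photons)
  attr(tab, "rng_seed") <- as.integer(seed)
  no_det <- res$detected_count == 0L || res$detected_weight <= 0
  attr(tab, "no_detected") <- no_det
  class(tab) <- c("offset_fraction_table", "data.frame")
  if (no_det) {
    warning("no detected photons: all offset bins are empty")
  }
  tab
}

#' Construct an offset-fraction table directly
#'
#' Builds the mixing table [simulate_cube()] consumes from explicit
#' per-offset bottom fractions and detected weights, bypassing photon
#' transport. Useful for cubes with a prescribed ground-truth crossover.
#'
#' @param offsets strictly increasing offsets, mm.
#' @param fraction_bottom per-offset bottom-layer fraction in `[0, 1]`
#'   (NA allowed for empty bins).
#' @param total_weight per-offset detected weight, >= 0.
#' @return An `offset_fraction_table`.
#' @export
offset_fraction_table <- function(offsets, fraction_bottom, total_weight) {
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  ok <- !is.na(fraction_bottom)
  if (any(fraction_bottom[ok] < 0 | fraction_bottom[ok] > 1)) {
    stop("fraction_bottom must lie in [0, 1]")
  }
  if (any(total_weight < 0)) stop("total_weight must be >= 0")
  tab <- data.frame(offset = offsets, fraction_bottom = fraction_bottom,
                    total_weight = total_weight,
                    n_detected = NA_integer_)
  attr(tab, "no_detected") <- all(total_weight == 0)
  class(tab) <- c("offset_fraction_table", "data.frame")
  tab
}

# Long-pass filter at the start of the sensor: the first n_filter channels
# carry no signal (they sit below the cutoff) and are truncated during
# preprocessing.
filter_transmission <- function(n_channels, n_filter = 0L) {
  trans <- rep(1, n_channels)
  if (n_filter > 0) trans[seq_len(min(n_filter, n_channels))] <- 0
  trans
}

#' Simulate a SORS hyperspectral cube
#'
#' Realizes the linear-mixture forward model: at offset i every
#' line-position spectrum is
#' `total_weight(i) * [f(i) * S_bottom + (1 - f(i)) * S_top] * exposure_scale`
#' plus a broad fluorescence baseline, then optional smile distortion,
#' shot noise, read noise and cosmic spikes.
#'
#' @param phantom a [phantom_spec()] (recorded as metadata).
#' @param refs a [reference_library()] whose axis length equals
#'   `acq$n_channels` (raw channel grid).
#' @param acq an [acquisition_config()].
#' @param noise a [noise_config()].
#' @param fractions an `offset_fraction_table` on the acquisition grid.
#' @return A `sors_cube`: list with `data` (array offsets x line positions
#'   x channels), `offsets`, `wavenumber` (NULL until calibrated), and
#'   `meta` recording configuration, ground truth and processing stages.
#' @export
simulate_cube <- function(phantom, refs, acq, noise, fractions) {
  stopifnot(inherits(refs, "reference_library"),
            inherits(acq, "acquisition_config"),
            inherits(noise, "noise_config"))
  offsets <- acq_offsets(acq)
  if (nrow(fractions) != length(offsets) ||
      max(abs(fractions$offset - offsets)) > 1e-9) {
    stop("fraction table offsets do not match the acquisition grid")
  }
  n_ch <- acq$n_channels
  if (length(refs$wavenumber) != n_ch) {
    stop("reference axis length does not match acq$n_channels")
  }
  s_top <- ref_top(refs)$intensity
  s_bot <- ref_bottom(refs)$intensity
  axis <- refs$wavenumber
  gauss <- function(par) {
    sigma <- par[2] / (2 * sqrt(2 * log(2)))
    exp(-(axis - par[1])^2 / (2 * sigma^2))
  }
  b_top <- gauss(noise$baseline_top)
  b_bot <- gauss(noise$baseline_bottom)
  trans <- filter_transmission(n_ch, acq$n_filter_channels)

  n_off <- acq$n_offsets; n_row <- acq$n_line_positions
  cube <- array(0, dim = c(n_off, n_row, n_ch))
  f <- fractions$fraction_bottom
  w <- fractions$total_weight
  for (i in seq_len(n_off)) {
    fi <- f[i]
    if (is.na(fi) || w[i] <= 0) next
    mix <- fi * s_bot + (1 - fi) * s_top
    base <- noise$baseline_amplitude * (fi * b_bot + (1 - fi) * b_top)
    clean <- w[i] * acq$exposure_scale * (mix + base) * trans
    if (any(clean < 0)) {
      warning("negative clean intensities clamped to 0")
      clean <- pmax(clean, 0)
    }
    for (j in seq_len(n_row)) cube[i, j, ] <- clean
  }

  # spectrometer smile: per-row channel shift
  shifts <- polyval_inc(noise$smile_coefficients, seq_len(n_row) - 1)
  if (any(shifts != 0)) {
    px <- seq_len(n_ch)
    for (j in seq_len(n_row)) {
      if (shifts[j] == 0) next
      for (i in seq_len(n_off)) {
        cube[i, j, ] <- approx(px, cube[i, j, ], xout = px - shifts[j],
                               rule = 2)$y
      }
    }
  }

  if (noise$shot_noise_enabled) {
    cube[] <- with_local_seed(stage_seed(noise$rng_seed, "shot"),
                              rpois(length(cube), lambda = pmin(cube, 1e9)))
  }
  if (noise$read_noise_sd > 0) {
    cube <- cube + with_local_seed(stage_seed(noise$rng_seed, "read"),
                                   rnorm(length(cube), sd = noise$read_noise_sd))
  }
  if (noise$cosmic_rate > 0) {
    cube <- with_local_seed(stage_seed(noise$rng_seed, "cosmic"), {
      for (i in seq_len(n_off)) {
        k <- rpois(1, noise$cosmic_rate)
        if (k > 0) {
          rows <- sample.int(n_row, k, replace = TRUE)
          chans <- sample.int(n_ch, k, replace = TRUE)
          amps <- runif(k, noise$cosmic_amplitude_range[1],
                        noise$cosmic_amplitude_range[2])
          for (s in seq_len(k)) {
            cube[i, rows[s], chans[s]] <- cube[i, rows[s], chans[s]] + amps[s]
          }
        }
      }
      cube
    })
  }

  structure(list(data = cube, offsets = offsets, wavenumber = NULL,
                 meta = list(phantom = phantom, acq = acq, noise = noise,
                             fractions = fractions,
                             stages = "raw", snv = FALSE)),
            class = "sors_cube")
}

#' @export
print.sors_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sors_cube> %d offsets x %d line positions x %d channels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  offsets %.2f-%.2f mm; stages: %s\n", min(x$offsets),
              max(x$offsets), paste(x$meta$stages, collapse = " -> ")))
  invisible(x)
}

#' @export
dim.sors_cube <- function(x) dim(x$data)

#' Synthesize calibration frames
#'
#' Builds the two calibration acquisitions the preprocessing chain needs:
#' a wavenumber-standard frame with narrow bands at known pixels (rows
#' shifted by the smile polynomial) and a system-response frame holding a
#' smooth spectral-response curve replicated per row.
#'
#' @param acq an [acquisition_config()].
#' @param band_pixels 0-based channel positions of the standard's bands.
#' @param smile_coefficients polynomial (increasing degree) of the per-row
#'   channel shift.
#' @param noise optional [noise_config()] supplying read noise.
#' @param band_fwhm_px band width, pixels.
#' @param band_amplitude band height, counts.
#' @param response_curve per-channel smooth response (default a broad
#'   bell-shaped sensitivity curve).
#' @return List with `wavenumber_frame` and `response_frame`, both
#'   matrices of `n_line_positions` rows by `n_channels` columns.
#' @export
make_calibration_frames <- function(acq, band_pixels,
                                    smile_coefficients = 0,
                                    noise = NULL,
                                    band_fwhm_px = 3,
                                    band_amplitude = 1e4,
                                    response_curve = NULL) {
  n_ch <- acq$n_channels; n_row <- acq$n_line_positions
  if (any(band_pixels < 0 | band_pixels > n_ch - 1)) {
    stop("band_pixels outside channel range")
  }
  px <- seq_len(n_ch) - 1
  sigma <- band_fwhm_px / (2 * sqrt(2 * log(2)))
  base <- rep(0, n_ch)
  for (b in band_pixels) base <- base + band_amplitude * exp(-(px - b)^2 / (2 * sigma^2))
  shifts <- polyval_inc(smile_coefficients, seq_len(n_row) - 1)
  wn_frame <- matrix(0, n_row, n_ch)
  for (j in seq_len(n_row)) {
    wn_frame[j, ] <- if (shifts[j] == 0) base else {
      approx(px, base, xout = px - shifts[j], rule = 2)$y
    }
  }
  if (is.null(response_curve)) {
    response_curve <- 0.4 + 0.6 * exp(-((px - 0.55 * n_ch) / (0.35 * n_ch))^2)
  }
  if (length(response_curve) != n_ch) stop("response_curve length mismatch")
  resp_frame <- matrix(rep(response_curve, each = n_row), n_row, n_ch)
  if (!is.null(noise) && noise$read_noise_sd > 0) {
    wn_frame <- wn_frame +
      with_local_seed(stage_seed(noise$rng_seed, "read"),
                      rnorm(length(wn_frame), sd = noise$read_noise_sd))
  }
  list(wavenumber_frame = wn_frame, response_frame = resp_frame)
}
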