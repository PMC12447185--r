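#' Truncate leading spectral channels
#'
#' Removes the first `n_drop` channels of a frame (rows = line positions,
#' columns = channels), the region below the long-pass filter cutoff.
#' With the conventional 1024-channel frames and `n_drop = 120` this
#' leaves 904 wavenumber values.
#'
#' @param frame numeric matrix, rows x channels.
#' @param n_drop channels to drop from the front (default 120).
#' @return The truncated matrix.
#' @export
truncate_low_channels <- function(frame, n_drop = 120L) {
  frame <- as.matrix(frame)
  if (n_drop < 0) stop("n_drop must be >= 0")
  if (n_drop >= ncol(frame)) stop("n_drop must be smaller than the channel count")
  if (n_drop == 0L) return(frame)
  frame[, -seq_len(n_drop), drop = FALSE]
}

#' Remove cosmic ray spikes from a frame
#'
#' Detects spikes per spectrum from the residual against a running median:
#' a channel is flagged when the modified z-score (median/MAD) of that
#' residual exceeds `z_threshold` and the residual also exceeds
#' `min_ratio` of the local median level. Because the running median
#' annihilates only features narrower than half its window, smooth Raman
#' bands leave near-zero residual and are never flagged; cosmic spikes
#' (one or two channels) stand out fully. Flagged runs are replaced by
#' linear interpolation of the nearest untouched neighbors.
#'
#' @param frame numeric matrix, rows x channels.
#' @param z_threshold modified z-score threshold (default 8).
#' @param window odd running-median window, >= 3 (default 5).
#' @param min_ratio minimum spike prominence relative to the local median
#'   level (default 0.2); guards band apexes in very low-noise spectra.
#' @return The despiked matrix; attribute `n_spikes` counts replaced
#'   channels.
#' @export
remove_cosmic_rays <- function(frame, z_threshold = 8, window = 5L,
                               min_ratio = 0.2) {
  frame <- as.matrix(frame)
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  n_ch <- ncol(frame)
  if (n_ch < window + 2) return(structure(frame, n_spikes = 0L))
  total <- 0L
  for (j in seq_len(nrow(frame))) {
    x <- frame[j, ]
    local <- stats::runmed(x, window)
    resid <- x - local
    med <- median(resid)
    scale <- mad(resid)
    if (scale <= 0) scale <- mean(abs(resid - med)) / 0.7979  # MAD degenerate
    if (scale <= 0) next
    z <- abs(resid - med) / scale
    bad <- (z > z_threshold) & (resid > min_ratio * (abs(local) + 1e-12))
    if (!any(bad)) next
    good <- which(!bad)
    if (length(good) < 2) next
    idx <- which(bad)
    x[idx] <- approx(good, x[good], xout = idx, rule = 2)$y
    frame[j, ] <- x
    total <- total + length(idx)
  }
  structure(frame, n_spikes = total)
}

# Intensity-weighted band centroid (0-based channel units) inside a
# column window; offset-subtracted so flat background does not bias it.
band_centroid <- function(x, cols) {
  w <- x[cols] - min(x[cols])
  if (sum(w) <= 0) return(NA_real_)
  sum(w * (cols - 1)) / sum(w)
}

#' Estimate spectrometer smile from a calibration frame
#'
#' Computes the centroid of one strong band per spatial row and returns
#' per-row channel shifts relative to row 1, smoothed by a quadratic fit
#' in row index (CCD smile is well described by a low-order curve).
#'
#' @param calibration_frame numeric matrix, rows x channels, containing
#'   exactly one strong band inside `band_window` in every row.
#' @param band_window integer column range (e.g. `391:431`) bracketing the
#'   band.
#' @param snr_floor minimum band prominence over the window median for a
#'   row's centroid to count.
#' @return Numeric per-row shifts, fractional channels.
#' @export
estimate_smile <- function(calibration_frame, band_window, snr_floor = 5) {
  fr <- as.matrix(calibration_frame)
  band_window <- as.integer(band_window)
  if (any(band_window < 1 | band_window > ncol(fr))) {
    stop("band_window outside channel range")
  }
  cents <- numeric(nrow(fr))
  for (j in seq_len(nrow(fr))) {
    seg <- fr[j, band_window]
    noise <- max(mad(seg), 1e-12)
    if ((max(seg) - median(seg)) < snr_floor * noise) {
      stop(sprintf("no usable calibration band in row %d", j))
    }
    cents[j] <- band_centroid(fr[j, ], band_window)
  }
  raw_shift <- cents - cents[1]
  row0 <- seq_along(raw_shift) - 1
  fit <- lm(raw_shift ~ row0 + I(row0^2))
  as.numeric(predict(fit))
}

#' Correct spectrometer smile
#'
#' Resamples each row by its negative shift (linear interpolation, edge
#' channels extended by nearest value), undoing the distortion returned by
#' [estimate_smile()].
#'
#' @param frame numeric matrix, rows x channels.
#' @param shifts per-row fractional-channel shifts (length = rows).
#' @return The corrected matrix.
#' @export
correct_smile <- function(frame, shifts) {
  frame <- as.matrix(frame)
  if (length(shifts) != nrow(frame)) stop("shifts length must equal row count")
  px <- seq_len(ncol(frame))
  for (j in seq_len(nrow(frame))) {
    if (shifts[j] == 0) next
    frame[j, ] <- approx(px, frame[j, ], xout = px + shifts[j], rule = 2)$y
  }
  frame
}

#' Calibrate the pixel-to-wavenumber axis
#'
#' Locates band centroids of a wavenumber-standard frame (row-averaged,
#' assumed smile-corrected), pairs them in order with the standard's known
#' band positions, and fits a least-squares polynomial from 0-based pixel
#' index to wavenumber.
#'
#' @param calibration_frame numeric matrix, rows x channels.
#' @param known_bands known band positions, cm^-1, in increasing order.
#' @param degree polynomial degree (default 3); needs at least
#'   `degree + 1` detected bands.
#' @param peak_min_frac detection threshold as a fraction of the tallest
#'   band (default 0.2).
#' @param centroid_halfwidth channels on each side of a detected maximum
#'   used for its centroid (default 5).
#' @return An object of class `wavenumber_axis`: list with `values`
#'   (cm^-1 per channel of the frame), `coefficients` (increasing degree)
#'   and `band_pixels` (detected centroids). The axis must come out
#'   strictly increasing.
#' @export
calibrate_wavenumber <- function(calibration_frame, known_bands, degree = 3L,
                                 peak_min_frac = 0.2, centroid_halfwidth = 5L) {
  fr <- as.matrix(calibration_frame)
  spec <- colMeans(fr)
  pk <- pracma::findpeaks(spec, minpeakheight = peak_min_frac * max(spec),
                          minpeakdistance = 2 * centroid_halfwidth + 1)
  if (is.null(pk)) stop("no calibration bands detected")
  locs <- sort(pk[, 2])
  if (length(locs) < degree + 1) {
    stop(sprintf("detected %d bands; need at least %d for degree %d",
                 length(locs), degree + 1, degree))
  }
  if (length(locs) != length(known_bands)) {
    stop(sprintf("detected %d bands but %d known band positions supplied",
                 length(locs), length(known_bands)))
  }
  cents <- vapply(locs, function(l) {
    cols <- max(1, l - centroid_halfwidth):min(ncol(fr), l + centroid_halfwidth)
    band_centroid(spec, cols)
  }, numeric(1))
  fit <- lm(known_bands ~ poly(cents, degree = degree, raw = TRUE))
  coefs <- as.numeric(coef(fit))
  px <- seq_len(ncol(fr)) - 1
  values <- polyval_inc(coefs, px)
  if (any(diff(values) <= 0)) {
    stop("calibrated wavenumber axis is not strictly increasing")
  }
  structure(list(values = values, coefficients = coefs,
                 band_pixels = cents, degree = as.integer(degree)),
            class = "wavenumber_axis")
}

#' Build the system-response correction
#'
#' Compares the row-averaged measured response of a certified
#' relative-intensity standard with its certified curve and returns a
#' per-channel multiplicative gain, normalized to unit mean. Applying the
#' gain to the measured response reproduces the certified curve up to one
#' scalar.
#'
#' @param response_frame numeric matrix, rows x channels, from imaging the
#'   intensity standard.
#' @param certified_curve certified per-channel relative intensity, > 0.
#' @return Numeric per-channel gain, unit mean.
#' @export
build_response_correction <- function(response_frame, certified_curve) {
  fr <- as.matrix(response_frame)
  if (length(certified_curve) != ncol(fr)) {
    stop("certified_curve length must equal channel count")
  }
  if (any(certified_curve <= 0)) stop("certified_curve must be > 0")
  measured <- colMeans(fr)
  if (any(measured <= 0)) stop("nonpositive measured response")
  gain <- certified_curve / measured
  gain / mean(gain)
}

#' Bubble-fill fluorescence baseline removal
#'
#' Estimates a fluorescence baseline by recursively fitting the largest
#' circle ("bubble") that slides up under the spectrum between successive
#' contact points, stopping once an interval is narrower than
#' `min_bubble_width` channels. Intervals touching the spectrum edge use
#' edge-aligned half bubbles so the baseline can rise at the ends. The
#' intensity axis is rescaled to channel units before the circle geometry
#' is applied. The baseline never exceeds the spectrum, so the recovered
#' Raman signal is non-negative.
#'
#' @param spectrum a [sors_spectrum()] or numeric vector.
#' @param min_bubble_width minimum bubble width, channels, >= 3. The
#'   default 75 is wider than any Raman band yet well below the curvature
#'   scale of a fluorescence background.
#' @return List with `raman` and `baseline`, of the same type as the
#'   input.
#' @export
remove_baseline_bubble <- function(spectrum, min_bubble_width = 75L) {
  x <- spectrum_intensity(spectrum)
  n <- length(x)
  if (min_bubble_width < 3) stop("min_bubble_width must be >= 3")
  if (n < min_bubble_width) stop("spectrum shorter than min_bubble_width")
  rng <- max(x) - min(x)
  if (rng == 0) {
    baseline <- x
  } else {
    # de-tilt with the endpoint chord, then scale intensities to channel
    # units so circle geometry is meaningful
    chord <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
    y <- x - chord
    yscale <- (max(y) - min(y))
    if (yscale == 0) yscale <- 1
    yv <- (y - min(y)) / yscale * (n - 1)
    base_y <- rep(-Inf, n)
    # Interval endpoints are contact points of earlier bubbles, except the
    # spectrum edges, which start uncontacted (flags le/re): an interval
    # with an uncontacted edge uses an edge-aligned half bubble (apex at
    # the edge) and may touch at that edge, which anchors it. Ordinary
    # touches are interior and split the interval.
    queue <- list(list(l = 1L, r = n, le = TRUE, re = TRUE))
    while (length(queue)) {
      iv <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      l <- iv$l; r <- iv$r
      w <- r - l
      # narrow interior intervals are done: both endpoints are contact
      # points, so finish them with the connecting chord (the limiting
      # maximal bubble). Intervals still holding an uncontacted spectrum
      # edge are processed regardless of width so the baseline gets
      # anchored at the ends.
      if (w + 1 < min_bubble_width && !iv$le && !iv$re) {
        if (w >= 1) {
          chord_y <- yv[l] + (yv[r] - yv[l]) * (0:w) / w
          base_y[l:r] <- pmax(base_y[l:r], pmin(chord_y, yv[l:r]))
        }
        next
      }
      if (w < 1) next
      idx <- l:r
      rel <- idx - l
      arc <- if (iv$le && !iv$re) {
        sqrt(pmax(0, w^2 - rel^2))             # apex at the left edge
      } else if (iv$re && !iv$le) {
        sqrt(pmax(0, w^2 - (w - rel)^2))       # apex at the right edge
      } else {
        R <- w / 2
        sqrt(pmax(0, R^2 - (rel - R)^2))       # centered bubble
      }
      lift <- yv[idx] - arc
      cand <- if (w >= 2) seq(2L, w) else integer(0)  # relative indices
      if (iv$le) cand <- c(1L, cand)
      if (iv$re) cand <- c(cand, w + 1L)
      if (length(cand) == 0) next
      k0 <- cand[which.min(lift[cand])]
      i0 <- idx[k0]
      base_y[idx] <- pmax(base_y[idx], lift[k0] + arc)
      if (i0 == l) {
        queue[[length(queue) + 1L]] <- list(l = l, r = r, le = FALSE,
                                            re = iv$re)
      } else if (i0 == r) {
        queue[[length(queue) + 1L]] <- list(l = l, r = r, le = iv$le,
                                            re = FALSE)
      } else {
        queue[[length(queue) + 1L]] <- list(l = l, r = i0, le = iv$le,
                                            re = FALSE)
        queue[[length(queue) + 1L]] <- list(l = i0, r = r, le = FALSE,
                                            re = iv$re)
      }
    }
    baseline <- base_y / (n - 1) * yscale + min(y) + chord
    baseline <- pmin(baseline, x)
  }
  raman <- x - baseline
  if (inherits(spectrum, "sors_spectrum")) {
    list(raman = sors_spectrum(spectrum$wavenumber, raman),
         baseline = sors_spectrum(spectrum$wavenumber, baseline))
  } else {
    list(raman = raman, baseline = baseline)
  }
}

#' Standard normal variate normalization
#'
#' Centers a spectrum to zero mean and scales it to unit population
#' standard deviation, the conventional chemometrics definition.
#'
#' @param spectrum a [sors_spectrum()] or numeric vector with nonzero
#'   spread.
#' @return The normalized spectrum, same type as the input.
#' @export
snv <- function(spectrum) {
  x <- spectrum_intensity(spectrum)
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("constant spectrum: SNV undefined (zero variance)")
  out <- (x - mean(x)) / s
  if (inherits(spectrum, "sors_spectrum")) {
    sors_spectrum(spectrum$wavenumber, out)
  } else {
    out
  }
}

#' Bundle calibration products for the preprocessing chain
#'
#' @param wavenumber_axis a [calibrate_wavenumber()] result (or NULL to
#'   skip axis assignment).
#' @param smile_shifts per-row shifts from [estimate_smile()] (or NULL).
#' @param response_correction per-channel gain from
#'   [build_response_correction()] (or NULL).
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(wavenumber_axis = NULL, smile_shifts = NULL,
                            response_correction = NULL) {
  if (!is.null(response_correction) && any(response_correction <= 0)) {
    stop("response_correction must be > 0 elementwise")
  }
  structure(list(wavenumber_axis = wavenumber_axis,
                 smile_shifts = smile_shifts,
                 response_correction = response_correction),
            class = "calibration_set")
}

#' Derive a calibration set from calibration frames
#'
#' Runs the calibration half of the chain: truncates both calibration
#' frames, estimates smile on the wavenumber-standard frame, corrects it,
#' fits the pixel-to-wavenumber polynomial and builds the system-response
#' gain.
#'
#' @param wavenumber_frame,response_frame raw calibration matrices.
#' @param known_bands band positions of the wavenumber standard, cm^-1.
#' @param certified_curve certified relative-intensity curve for the
#'   retained channels.
#' @param n_drop leading channels to truncate.
#' @param band_window column range (after truncation) bracketing the band
#'   used for smile estimation; defaults to +-15 channels around the
#'   strongest column.
#' @param degree wavenumber polynomial degree.
#' @return A [calibration_set()].
#' @export
build_calibration_set <- function(wavenumber_frame, response_frame,
                                  known_bands, certified_curve,
                                  n_drop = 120L, band_window = NULL,
                                  degree = 3L) {
  wnf <- truncate_low_channels(wavenumber_frame, n_drop)
  rsf <- truncate_low_channels(response_frame, n_drop)
  if (is.null(band_window)) {
    strongest <- which.max(colMeans(wnf))
    band_window <- max(1, strongest - 15):min(ncol(wnf), strongest + 15)
  }
  shifts <- estimate_smile(wnf, band_window)
  wnf <- correct_smile(wnf, shifts)
  axis <- calibrate_wavenumber(wnf, known_bands, degree = degree)
  gain <- build_response_correction(rsf, certified_curve)
  calibration_set(wavenumber_axis = axis, smile_shifts = shifts,
                  response_correction = gain)
}

#' Preprocess a SORS cube
#'
#' Applies the full chain, in order: channel truncation, cosmic ray
#' removal, smile correction, wavenumber axis assignment, system-response
#' correction, bubble baseline removal, and SNV normalization. Stage
#' provenance is recorded in the cube metadata; stages whose calibration
#' input is NULL are skipped.
#'
#' @param cube a `sors_cube` from [simulate_cube()] or [read_sors_cube()].
#' @param cal a [calibration_set()].
#' @param params list of stage parameters: `n_drop` (default 120, 0 for
#'   cubes without a filter region), `z_threshold`, `window`,
#'   `min_bubble_width`, `despike`, `baseline` (logical switches).
#' @return The processed `sors_cube` with `wavenumber` set (when
#'   calibrated) and `meta$snv = TRUE`.
#' @export
preprocess_cube <- function(cube, cal = calibration_set(), params = list()) {
  stopifnot(inherits(cube, "sors_cube"), inherits(cal, "calibration_set"))
  p <- modifyList(list(n_drop = cube$meta$acq$n_filter_channels %||% 120L,
                       z_threshold = 8, window = 5L,
                       min_bubble_width = 75L,
                       despike = TRUE, baseline = TRUE), params)
  d <- dim(cube$data)
  n_off <- d[1]; n_row <- d[2]
  stages <- cube$meta$stages

  run_framewise <- function(data, fun, out_ch = dim(data)[3]) {
    out <- array(0, dim = c(n_off, n_row, out_ch))
    for (i in seq_len(n_off)) {
      fr <- matrix(data[i, , ], nrow = n_row)
      out[i, , ] <- fun(fr, i)
    }
    out
  }

  if (p$n_drop > 0) {
    cube$data <- run_framewise(cube$data,
                               function(fr, i) truncate_low_channels(fr, p$n_drop),
                               out_ch = d[3] - p$n_drop)
    stages <- c(stages, sprintf("truncate[%d]", p$n_drop))
  }
  if (isTRUE(p$despike)) {
    spikes <- 0L
    cube$data <- run_framewise(cube$data, function(fr, i) {
      fr2 <- remove_cosmic_rays(fr, p$z_threshold, p$window)
      spikes <<- spikes + attr(fr2, "n_spikes")
      fr2
    })
    stages <- c(stages, sprintf("despike[%d]", spikes))
    cube$meta$n_spikes_removed <- spikes
  }
  if (!is.null(cal$smile_shifts)) {
    cube$data <- run_framewise(cube$data,
                               function(fr, i) correct_smile(fr, cal$smile_shifts))
    stages <- c(stages, "smile")
  }
  if (!is.null(cal$wavenumber_axis)) {
    if (length(cal$wavenumber_axis$values) != dim(cube$data)[3]) {
      stop("calibration axis length does not match cube channels")
    }
    cube$wavenumber <- cal$wavenumber_axis$values
    stages <- c(stages, "wavenumber")
  }
  if (!is.null(cal$response_correction)) {
    gain <- cal$response_correction
    if (length(gain) != dim(cube$data)[3]) {
      stop("response correction length does not match cube channels")
    }
    cube$data <- run_framewise(cube$data,
                               function(fr, i) sweep(fr, 2, gain, `*`))
    stages <- c(stages, "response")
  }
  if (isTRUE(p$baseline)) {
    mbw <- min(p$min_bubble_width, dim(cube$data)[3] - 1)
    cube$data <- run_framewise(cube$data, function(fr, i) {
      for (j in seq_len(nrow(fr))) {
        fr[j, ] <- remove_baseline_bubble(fr[j, ], mbw)$raman
      }
      fr
    })
    stages <- c(stages, "baseline")
  }
  n_empty <- 0L
  cube$data <- run_framewise(cube$data, function(fr, i) {
    for (j in seq_len(nrow(fr))) {
      s <- sqrt(mean((fr[j, ] - mean(fr[j, ]))^2))
      if (s == 0) {
        # empty bin (no detected photons, no noise): leave all-zero and
        # let downstream similarity analysis flag it rather than abort
        n_empty <<- n_empty + 1L
        fr[j, ] <- 0
      } else {
        fr[j, ] <- (fr[j, ] - mean(fr[j, ])) / s
      }
    }
    fr
  })
  stages <- c(stages, "snv")
  cube$meta$n_empty_spectra <- n_empty
  cube$meta$stages <- stages
  cube$meta$snv <- TRUE
  cube
}

`%||%` <- function(a, b) if (is.null(a)) b else a
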