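test_that("channel truncation drops exactly the filter region", {
  fr <- matrix(rnorm(3 * 1024), nrow = 3)
  out <- truncate_low_channels(fr, 120)
  expect_equal(ncol(out), 904L)
  expect_equal(out, fr[, 121:1024])
  expect_equal(truncate_low_channels(fr, 0), fr)
  expect_error(truncate_low_channels(fr, 1024), "smaller than")
})

test_that("cosmic spikes are removed without touching real bands", {
  ax <- tiny_axis(904)
  clean <- make_reference_spectrum(list(c(700, 12, 800), c(1100, 10, 1000),
                                        c(1500, 18, 600)), ax)$intensity + 50
  amp <- max(clean)

  spiked <- clean
  spiked[400] <- spiked[400] + 100 * clean[400]
  out <- remove_cosmic_rays(rbind(spiked), z_threshold = 8, window = 5)
  expect_equal(attr(out, "n_spikes") >= 1, TRUE)
  expect_lt(max(abs(out[1, ] - clean)), 0.01 * amp)

  # spike-free spectra pass through unchanged
  out2 <- remove_cosmic_rays(rbind(clean))
  expect_equal(out2[1, ], clean)
  expect_equal(attr(out2, "n_spikes"), 0L)

  # two adjacent spiked channels are both replaced
  dbl <- clean
  dbl[650:651] <- dbl[650:651] + c(80, 120) * amp
  out3 <- remove_cosmic_rays(rbind(dbl))
  expect_lt(max(abs(out3[1, ] - clean)), 0.05 * amp)
})

test_that("smile is estimated and corrected to sub-0.1-channel accuracy", {
  acq <- acquisition_config(n_offsets = 2L, n_line_positions = 42L,
                            n_channels = 512L, n_filter_channels = 0L)
  frames <- make_calibration_frames(acq, band_pixels = 300,
                                    smile_coefficients = c(0, 0, 0.002))
  wf <- frames$wavenumber_frame

  sh0 <- estimate_smile(make_calibration_frames(acq, 300)$wavenumber_frame,
                        band_window = 271:331)
  expect_lt(max(abs(sh0)), 0.05)

  sh <- estimate_smile(wf, band_window = 271:331)
  expect_equal(sh[42], 0.002 * 41^2, tolerance = 0.1)

  corrected <- correct_smile(wf, sh)
  cents <- apply(corrected[, 271:331], 1, function(v) {
    w <- v - min(v); sum(w * seq_along(w)) / sum(w)
  })
  expect_lt(max(cents) - min(cents), 0.1)

  # integer shift moves a row exactly (interior channels)
  fr <- matrix(sin(seq_len(512) / 9), nrow = 1)
  out <- correct_smile(fr, shifts = -2)
  expect_equal(out[1, 3:510], fr[1, 1:508], tolerance = 1e-12)
  expect_equal(correct_smile(fr, 0), fr)

  blank <- wf; blank[7, ] <- 0
  expect_error(estimate_smile(blank, band_window = 271:331), "row 7")
})

test_that("wavenumber calibration recovers known pixel-to-cm^-1 maps", {
  acq <- acquisition_config(n_offsets = 2L, n_line_positions = 4L,
                            n_channels = 904L, n_filter_channels = 0L)
  # exact linear map: wn = 380 + 1.9 * pixel
  px_bands <- c(60, 200, 330, 480, 640, 810)
  known_lin <- 380 + 1.9 * px_bands
  frames <- make_calibration_frames(acq, band_pixels = px_bands)
  ax1 <- calibrate_wavenumber(frames$wavenumber_frame, known_lin, degree = 1)
  expect_equal(ax1$coefficients, c(380, 1.9), tolerance = 1e-6)

  # cubic map, degree 3: max axis error < 0.1 cm^-1
  cub <- function(p) 400 + 1.85 * p + 2e-5 * p^2 - 1e-8 * p^3
  known_cub <- cub(px_bands)
  ax3 <- calibrate_wavenumber(frames$wavenumber_frame, known_cub, degree = 3)
  expect_lt(max(abs(ax3$values - cub(0:903))), 0.1)
  expect_true(all(diff(ax3$values) > 0))

  two <- make_calibration_frames(acq, band_pixels = c(200, 600))
  expect_error(calibrate_wavenumber(two$wavenumber_frame, c(700, 1500),
                                    degree = 3), "need at least")
})

test_that("system-response gain inverts a known distortion", {
  acq <- acquisition_config(n_offsets = 2L, n_line_positions = 4L,
                            n_channels = 256L, n_filter_channels = 0L)
  px <- 0:255
  certified <- 0.5 + 0.5 * exp(-((px - 140) / 90)^2)

  same <- make_calibration_frames(acq, band_pixels = 10,
                                  response_curve = certified)
  g0 <- build_response_correction(same$response_frame, certified)
  expect_lt(max(g0) - min(g0), 1e-10)

  d <- 1 + 0.3 * sin(px / 40)
  distorted <- make_calibration_frames(acq, band_pixels = 10,
                                       response_curve = certified * d)
  g <- build_response_correction(distorted$response_frame, certified)
  expect_equal(g / mean(g), (1 / d) / mean(1 / d), tolerance = 1e-10)

  bad <- same$response_frame; bad[, 5] <- 0
  expect_error(build_response_correction(bad, certified), "onpositive")
})

test_that("bubble baseline hugs smooth backgrounds and preserves peaks", {
  n <- 904
  ch <- seq_len(n)
  # smooth concave fluorescence-like background, no peaks
  base <- 1000 * exp(-((ch - 420) / 500)^2)
  out <- remove_baseline_bubble(base, min_bubble_width = 50)
  expect_lt(max(abs(out$raman)), 0.01 * max(base))
  expect_true(all(out$baseline <= base + 1e-9))

  # background plus one narrow peak: peak height recovered within 5%
  peak <- 800 * exp(-((ch - 500)^2) / (2 * (10 / 2.355)^2))
  out2 <- remove_baseline_bubble(base + peak, min_bubble_width = 50)
  expect_equal(max(out2$raman[450:550]), 800, tolerance = 0.05)
  expect_true(all(out2$raman >= -1e-9))

  zero <- remove_baseline_bubble(rep(0, 200), min_bubble_width = 20)
  expect_equal(zero$raman, rep(0, 200))
  expect_equal(zero$baseline, rep(0, 200))

  expect_error(remove_baseline_bubble(rep(1, 10), min_bubble_width = 50),
               "shorter")
})

test_that("SNV normalizes with the population standard deviation", {
  expect_equal(snv(c(1, 2, 3)), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  x <- rnorm(300, mean = 5, sd = 2)
  y <- snv(x)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(y^2)), 1, tolerance = 1e-12)
  expect_equal(snv(y), y, tolerance = 1e-12)          # idempotence
  expect_equal(snv(3.2 * x + 7), y, tolerance = 1e-12) # affine invariance
  expect_error(snv(c(5, 5, 5)), "zero variance")
})

test_that("the full chain reduces a clean pure-material cube to its SNV signature", {
  acq <- micro_acq(n_offsets = 6L, n_channels = 256L)
  refs <- micro_refs(acq)
  offsets <- acq_offsets(acq)
  ft <- offset_fraction_table(offsets, rep(0, 6), rep(0.05, 6))
  cube <- simulate_cube(phantom_spec("pure", 1, 0.1, 7), refs, acq,
                        noise_config_off(), ft)
  proc <- preprocess_cube(cube, calibration_set(),
                          params = list(n_drop = 0, min_bubble_width = 60))
  target <- snv(remove_baseline_bubble(ref_top(refs)$intensity, 60)$raman)
  expect_lt(max(abs(proc$data[3, 2, ] - target)), 1e-3 * max(abs(target)))
  expect_true(proc$meta$snv)

  # with a modest fluorescence baseline added the chain still recovers the
  # signature to a few percent (bubble leakage under the bands)
  nb <- noise_config(shot_noise_enabled = FALSE, read_noise_sd = 0,
                     cosmic_rate = 0, smile_coefficients = 0,
                     baseline_amplitude = 0.05)
  cube_b <- simulate_cube(phantom_spec("pure", 1, 0.1, 7), refs, acq, nb, ft)
  proc_b <- preprocess_cube(cube_b, calibration_set(),
                            params = list(n_drop = 0, min_bubble_width = 60))
  expect_lt(max(abs(proc_b$data[3, 2, ] - target)), 0.05 * max(abs(target)))

  # all corrections disabled on a clean, baseline-free cube: SNV only
  cube2 <- simulate_cube(phantom_spec("pure", 1, 0.1, 7), refs, acq,
                         noise_config_off(), ft)
  proc2 <- preprocess_cube(cube2, calibration_set(),
                           params = list(n_drop = 0, despike = FALSE,
                                         baseline = FALSE))
  expect_equal(proc2$data[2, 1, ], snv(cube2$data[2, 1, ]), tolerance = 1e-12)
})

test_that("artifact injection is undone to within 2% RMS of the clean result", {
  # instrument-scale spectral sampling; reduced offsets and line positions
  acq <- micro_acq(n_offsets = 10L, n_channels = 904L, n_line_positions = 6L)
  refs <- micro_refs(acq)
  ft <- logistic_fractions(acq_offsets(acq), s_star = 1.2)
  ph <- phantom_spec("nz", 1, 0.1, 7)
  noisy <- noise_config(shot_noise_enabled = FALSE, read_noise_sd = 0,
                        cosmic_rate = 1.5,
                        cosmic_amplitude_range = c(2e3, 2e4),
                        smile_coefficients = c(0, 0, 0.02),
                        baseline_amplitude = 0.4, rng_seed = 21L)
  cube_noisy <- simulate_cube(ph, refs, acq, noisy, ft)
  cube_clean <- simulate_cube(ph, refs, acq, noise_config_off(), ft)

  # calibration frames observed with the same smile
  frames <- make_calibration_frames(acq, band_pixels = c(140, 420, 740),
                                    smile_coefficients = c(0, 0, 0.02))
  shifts <- estimate_smile(frames$wavenumber_frame, band_window = 391:451)
  cal <- calibration_set(smile_shifts = shifts)
  params <- list(n_drop = 0, min_bubble_width = 75)
  proc_noisy <- preprocess_cube(cube_noisy, cal, params)
  proc_clean <- preprocess_cube(cube_clean, calibration_set(),
                                params = list(n_drop = 0, despike = FALSE,
                                              min_bubble_width = 75))
  rms <- sqrt(mean((proc_noisy$data - proc_clean$data)^2)) /
    sqrt(mean(proc_clean$data^2))
  expect_lt(rms, 0.02)
})
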