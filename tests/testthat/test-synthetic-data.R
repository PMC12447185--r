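test_that("reference spectra are Gaussian band sums with expected geometry", {
  ax <- tiny_axis(904)
  s <- make_reference_spectrum(list(c(1004, 10, 1.0)), ax)
  expect_equal(which.max(s$intensity), which.min(abs(ax - 1004)))
  expect_true(all(s$intensity >= 0))

  expect_equal(make_reference_spectrum(list(), ax)$intensity, rep(0, 904))

  # two equal-amplitude peaks symmetric about the axis midpoint
  mid <- (min(ax) + max(ax)) / 2
  s2 <- make_reference_spectrum(list(c(mid - 300, 20, 1), c(mid + 300, 20, 1)), ax)
  expect_equal(s2$intensity, rev(s2$intensity), tolerance = 1e-12)

  expect_warning(make_reference_spectrum(list(c(5000, 10, 1)), ax),
                 "outside axis")
  expect_error(make_reference_spectrum(list(c(1000, -1, 1)), ax), "fwhm")
})

test_that("photon transport: no top layer puts every conversion site below it", {
  acq <- micro_acq(n_offsets = 10L)
  ft <- sample_photon_paths(phantom_spec("bare", 0, 0.1, 7), acq,
                            n_photons = 2e4, seed = 7)
  ok <- !is.na(ft$fraction_bottom)
  expect_true(any(ok))
  expect_equal(ft$fraction_bottom[ok], rep(1, sum(ok)))
})

test_that("photon transport: an opaque top layer blocks detection", {
  acq <- micro_acq(n_offsets = 10L)
  expect_warning(
    ft <- sample_photon_paths(phantom_spec("opaque", 3, 1e6, 7), acq,
                              n_photons = 5e3, seed = 7),
    "no detected photons")
  expect_lt(sum(ft$total_weight), 1e-6)
  expect_true(attr(ft, "no_detected"))
})

test_that("bottom fraction grows with offset (up to Monte Carlo error)", {
  acq <- acquisition_config(n_offsets = 40L, n_line_positions = 2L,
                            n_channels = 8L, n_filter_channels = 0L)
  ft <- sample_photon_paths(phantom_spec("mid", 1.5, 0.1, 7), acq,
                            n_photons = 3e5, seed = 11)
  ok <- !is.na(ft$fraction_bottom) & ft$n_detected >= 100
  f <- ft$fraction_bottom[ok]
  iso <- stats::isoreg(seq_along(f), f)
  expect_lt(max(abs(iso$yf - f)), 0.02)
})

test_that("bottom fraction decreases with top-layer thickness (paired seeds)", {
  acq <- micro_acq(n_offsets = 16L, n_channels = 8L)
  thin <- sample_photon_paths(phantom_spec("a", 0.8, 0.1, 7), acq, 1e5, seed = 3)
  thick <- sample_photon_paths(phantom_spec("b", 2.0, 0.1, 7), acq, 1e5, seed = 3)
  ok <- !is.na(thin$fraction_bottom) & !is.na(thick$fraction_bottom) &
    thin$n_detected >= 50 & thick$n_detected >= 50
  se <- sqrt(thin$fraction_bottom * (1 - thin$fraction_bottom) / thin$n_detected) +
    sqrt(thick$fraction_bottom * (1 - thick$fraction_bottom) / thick$n_detected)
  expect_true(all(thick$fraction_bottom[ok] <=
                    thin$fraction_bottom[ok] + 2 * se[ok]))
})

test_that("cube simulation obeys the linear-mixture model exactly with noise off", {
  acq <- micro_acq(n_offsets = 8L)
  refs <- micro_refs(acq)
  ph <- phantom_spec("mix", 1, 0.1, 7)
  offsets <- acq_offsets(acq)

  # pure top layer: every spectrum is proportional to the top signature
  ft0 <- offset_fraction_table(offsets, rep(0, 8), rep(0.05, 8))
  noise <- noise_config_off()
  cube0 <- simulate_cube(ph, refs, acq, noise, ft0)
  expected <- 0.05 * acq$exposure_scale * ref_top(refs)$intensity
  for (i in c(1, 5)) {
    expect_equal(cube0$data[i, 2, ], expected, tolerance = 1e-12)
  }

  # general fractions, baseline on: exact linear combination plus baseline
  nb <- noise_config(shot_noise_enabled = FALSE, read_noise_sd = 0,
                     cosmic_rate = 0, smile_coefficients = 0,
                     baseline_amplitude = 1.5)
  ftm <- logistic_fractions(offsets, s_star = 0.9)
  cubem <- simulate_cube(ph, refs, acq, nb, ftm)
  ax <- refs$wavenumber
  g <- function(par) {
    sg <- par[2] / (2 * sqrt(2 * log(2)))
    exp(-(ax - par[1])^2 / (2 * sg^2))
  }
  i <- 4
  f <- ftm$fraction_bottom[i]
  manual <- ftm$total_weight[i] * acq$exposure_scale *
    (f * ref_bottom(refs)$intensity + (1 - f) * ref_top(refs)$intensity +
       1.5 * (f * g(nb$baseline_bottom) + (1 - f) * g(nb$baseline_top)))
  expect_equal(cubem$data[i, 1, ], manual, tolerance = 1e-12)
})

test_that("a default-geometry cube has dimensions 40 x 42 x 1024", {
  acq <- acquisition_config()
  refs <- default_reference_library(simulated_pixel_axis(1024, 120)$wavenumber)
  ft <- logistic_fractions(acq_offsets(acq), s_star = 3)
  cube <- simulate_cube(phantom_spec("full", 1.5, 0.1, 7), refs, acq,
                        noise_config_off(), ft)
  expect_equal(dim(cube), c(40L, 42L, 1024L))
})

test_that("identical seed and configuration reproduce cubes bit for bit", {
  acq <- micro_acq(n_offsets = 6L)
  refs <- micro_refs(acq)
  ph <- phantom_spec("det", 1, 0.1, 7)
  ft1 <- sample_photon_paths(ph, acq, 5e3, seed = 99)
  ft2 <- sample_photon_paths(ph, acq, 5e3, seed = 99)
  expect_identical(ft1, ft2)
  noise <- noise_config(rng_seed = 5L)
  c1 <- simulate_cube(ph, refs, acq, noise, ft1)
  c2 <- simulate_cube(ph, refs, acq, noise, ft2)
  expect_identical(c1$data, c2$data)
  # different seed produces different noise
  c3 <- simulate_cube(ph, refs, acq, noise_config(rng_seed = 6L), ft1)
  expect_false(identical(c1$data, c3$data))
})

test_that("calibration frames encode the injected smile", {
  acq <- acquisition_config(n_offsets = 2L, n_line_positions = 42L,
                            n_channels = 512L, n_filter_channels = 0L)
  fr0 <- make_calibration_frames(acq, band_pixels = c(100, 300),
                                 smile_coefficients = 0)
  expect_true(all(apply(fr0$wavenumber_frame, 2, function(col)
    max(col) - min(col)) < 1e-12))

  frq <- make_calibration_frames(acq, band_pixels = 300,
                                 smile_coefficients = c(0, 0, 0.002))
  cent <- function(v) {
    w <- v - min(v)
    sum(w * (seq_along(v) - 1)) / sum(w)
  }
  shift41 <- cent(frq$wavenumber_frame[42, 250:350]) -
    cent(frq$wavenumber_frame[1, 250:350])
  expect_equal(shift41, 0.002 * 41^2, tolerance = 0.05)

  frc <- make_calibration_frames(acq, band_pixels = 100,
                                 response_curve = rep(0.7, 512))
  expect_equal(as.numeric(frc$response_frame[13, ]), rep(0.7, 512))

  expect_error(make_calibration_frames(acq, band_pixels = 600), "range")
})

test_that("cubes survive a TIFF round trip with sidecar metadata", {
  acq <- micro_acq(n_offsets = 5L, n_channels = 64L)
  refs <- default_reference_library(tiny_axis(64))
  ft <- logistic_fractions(acq_offsets(acq), s_star = 0.5)
  cube <- simulate_cube(phantom_spec("io", 1, 0.1, 7), refs, acq,
                        noise_config(rng_seed = 2L), ft)
  dir <- withr::local_tempdir()
  write_sors_cube(cube, dir)
  back <- read_sors_cube(dir)
  expect_equal(dim(back), dim(cube))
  expect_equal(back$offsets, cube$offsets)
  # 32-bit float storage: relative error bounded by single precision
  expect_lt(max(abs(back$data - cube$data)) / max(abs(cube$data)), 1e-6)
  expect_equal(back$meta$phantom$thickness_t, 1)
})
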