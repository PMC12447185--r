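# Shared fixtures: everything is generated in code at test time.

tiny_axis <- function(n = 256) seq(400, 2100, length.out = n)

# Acquisition for fast cubes: full 40-offset grid, reduced spatial and
# spectral sampling, no filter region (n_drop = 0 downstream).
micro_acq <- function(n_offsets = 40L, n_line_positions = 4L,
                      n_channels = 192L, ...) {
  acquisition_config(n_offsets = n_offsets,
                     n_line_positions = n_line_positions,
                     n_channels = n_channels, n_filter_channels = 0L, ...)
}

micro_refs <- function(acq) default_reference_library(tiny_axis(acq$n_channels))

# Mixing table with a prescribed ground-truth crossover at s_star:
# logistic bottom fraction, exponentially decaying detected weight.
logistic_fractions <- function(offsets, s_star, width = 0.8,
                               w0 = 0.05, w_decay = 4) {
  offset_fraction_table(offsets,
                        fraction_bottom = 1 / (1 + exp(-(offsets - s_star) / width)),
                        total_weight = w0 * exp(-offsets / w_decay))
}

# First 0.5-upcrossing of a Monte Carlo fraction table, by linear
# interpolation (the ground truth a pipeline crossover is compared to).
fraction_crossing <- function(ft) {
  f <- ft$fraction_bottom
  ok <- !is.na(f)
  f[!ok] <- 0
  k <- which(f[-1] >= 0.5 & f[-length(f)] < 0.5)[1]
  if (is.na(k)) return(NA_real_)
  ft$offset[k] + (0.5 - f[k]) * (ft$offset[k + 1] - ft$offset[k]) /
    (f[k + 1] - f[k])
}

# Independent brute-force crossover oracle: sample the linearly
# interpolated difference curve on a dense grid, find the first
# positive-to-nonpositive cell, then polish the root inside that cell.
brute_force_crossover <- function(offsets, d, n_grid = 1e4) {
  f <- approxfun(offsets, d)
  g <- seq(min(offsets), max(offsets), length.out = n_grid)
  dg <- f(g)
  if (dg[1] <= 0) return(NA_real_)
  k <- which(dg[-1] <= 0 & dg[-length(dg)] > 0)[1]
  if (is.na(k)) return(NA_real_)
  if (dg[k + 1] == 0) return(g[k + 1])
  stats::uniroot(f, c(g[k], g[k + 1]), tol = 1e-13)$root
}

expect_no_na <- function(x) expect_false(anyNA(x))
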