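#' Spectral angle mapper
#'
#' Cosine similarity of two spectra across wavenumber channels:
#' `sum(R * S) / (sqrt(sum(R^2)) * sqrt(sum(S^2)))`. Returns +1 for
#' colinear spectra, 0 for linearly independent (orthogonal) ones, and
#' lies in `[-1, 1]` always.
#'
#' @param reference reference spectrum ([sors_spectrum()] or numeric).
#' @param measured measured spectrum, same length.
#' @return The SAM value.
#' @export
sam <- function(reference, measured) {
  r <- spectrum_intensity(reference)
  s <- spectrum_intensity(measured)
  if (length(r) != length(s)) stop("spectra have different lengths")
  nr <- sqrt(sum(r^2)); ns <- sqrt(sum(s^2))
  if (nr == 0 || ns == 0) stop("zero-norm spectrum in SAM")
  v <- sum(r * s) / (nr * ns)
  max(-1, min(1, v))
}

#' SAM-versus-offset curves for a preprocessed cube
#'
#' Computes the SAM of every line-position spectrum against the top and
#' bottom reference signatures and averages the per-spectrum values across
#' line positions at each offset (set `aggregate = "mean_spectrum"` to
#' instead take the SAM of the mean spectrum). Zero-norm spectra (empty
#' offset bins) are skipped; offsets with no valid spectrum get NA.
#'
#' @param cube a preprocessed `sors_cube` (`meta$snv` must be TRUE).
#' @param refs a [reference_library()] preprocessed identically to the
#'   measurements (baseline-removed, SNV).
#' @param aggregate `"mean_sam"` (default) or `"mean_spectrum"`.
#' @return A `sam_curve`: data frame with columns `offset`, `sam_top`,
#'   `sam_bottom`, `sam_total` and `n_spectra_averaged`.
#' @export
sam_curve <- function(cube, refs, aggregate = c("mean_sam", "mean_spectrum")) {
  stopifnot(inherits(cube, "sors_cube"), inherits(refs, "reference_library"))
  aggregate <- match.arg(aggregate)
  if (!isTRUE(cube$meta$snv)) {
    stop("cube is not preprocessed (SNV flag not set); run preprocess_cube()")
  }
  n_ch <- dim(cube$data)[3]
  if (length(refs$wavenumber) != n_ch) {
    stop("reference and measurement axes have different lengths")
  }
  if (is.numeric(cube$wavenumber) && length(cube$wavenumber) == n_ch &&
      max(abs(cube$wavenumber - refs$wavenumber)) > 1) {
    stop("reference and measurement wavenumber axes disagree")
  }
  r_top <- ref_top(refs)$intensity
  r_bot <- ref_bottom(refs)$intensity
  n_off <- dim(cube$data)[1]; n_row <- dim(cube$data)[2]
  s_top <- s_bot <- rep(NA_real_, n_off)
  n_used <- integer(n_off)
  for (i in seq_len(n_off)) {
    fr <- matrix(cube$data[i, , ], nrow = n_row)
    norms <- sqrt(rowSums(fr^2))
    ok <- norms > 0
    n_used[i] <- sum(ok)
    if (!any(ok)) next
    if (aggregate == "mean_sam") {
      s_top[i] <- mean((fr[ok, , drop = FALSE] %*% r_top) /
                         (norms[ok] * sqrt(sum(r_top^2))))
      s_bot[i] <- mean((fr[ok, , drop = FALSE] %*% r_bot) /
                         (norms[ok] * sqrt(sum(r_bot^2))))
    } else {
      m <- colMeans(fr[ok, , drop = FALSE])
      s_top[i] <- sam(r_top, m)
      s_bot[i] <- sam(r_bot, m)
    }
  }
  out <- data.frame(offset = cube$offsets, sam_top = s_top,
                    sam_bottom = s_bot, sam_total = s_top + s_bot,
                    n_spectra_averaged = n_used)
  class(out) <- c("sam_curve", "data.frame")
  out
}

#' Locate the SAM crossover offset
#'
#' Evaluates `D = sam_top - sam_bottom` on the offset grid and finds the
#' first sign change from positive to non-positive; the crossover offset
#' is obtained by linear interpolation of D between the bracketing grid
#' points. Trailing offsets with missing SAM values are ignored. Later
#' re-crossings are recorded but not reported as the crossover.
#'
#' When the detected light at large offsets has degenerated to noise, the
#' SAM difference fluctuates around zero and can cross it spuriously; a
#' crossing is therefore only accepted while the summed similarity
#' `sam_total` at the bracket stays above `min_sam_total`. Noise-only SAM
#' values scatter around 0 at a scale of about `1/sqrt(n_channels)`
#' (~0.03 at 904 channels), so the default floor of 0.2 sits several
#' noise standard deviations up while real crossovers show `sam_total`
#' near 1 or above. Set it to `-Inf` to accept any sign change.
#'
#' @param curve a `sam_curve` with at least 2 offsets.
#' @param min_sam_total minimum summed similarity at the bracket for a
#'   crossing (or the first grid point, for `below_grid`) to count as
#'   physical; default 0.2.
#' @return A `crossover_result`: list with `delta_s_co` (mm or NA),
#'   `bracket` (the two straddling grid offsets), `status` one of
#'   `"crossover_found"`, `"below_grid"` (D <= 0 already at the first
#'   offset: the crossover lies before the grid), `"none_detected"`, and
#'   `n_noise_crossings` (sign changes rejected by the floor).
#' @export
find_crossover <- function(curve, min_sam_total = 0.2) {
  stopifnot(inherits(curve, "data.frame"))
  ok <- is.finite(curve$sam_top) & is.finite(curve$sam_bottom)
  cv <- curve[ok, , drop = FALSE]
  if (nrow(cv) < 2) stop("need at least 2 offsets with finite SAM values")
  D <- cv$sam_top - cv$sam_bottom
  tot <- cv$sam_top + cv$sam_bottom
  res <- list(delta_s_co = NA_real_, bracket = c(NA_real_, NA_real_),
              plateau_offset = NA_real_, status = "none_detected",
              n_noise_crossings = 0L)
  class(res) <- "crossover_result"
  if (D[1] <= 0) {
    res$status <- if (tot[1] >= min_sam_total) "below_grid" else
      "none_detected"
    return(res)
  }
  sign_change <- which(D[-1] <= 0 & D[-length(D)] > 0)
  usable <- sign_change[pmin(tot[sign_change], tot[sign_change + 1]) >=
                          min_sam_total]
  res$n_noise_crossings <- length(sign_change) - length(usable)
  if (length(usable) == 0) {
    res$status <- "none_detected"
    return(res)
  }
  k <- usable[1]
  x1 <- cv$offset[k]; x2 <- cv$offset[k + 1]
  d1 <- D[k]; d2 <- D[k + 1]
  res$delta_s_co <- if (d2 == d1) x2 else x1 + d1 * (x2 - x1) / (d1 - d2)
  res$bracket <- c(x1, x2)
  res$status <- "crossover_found"
  res
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf("<crossover_result> status: %s", x$status))
  if (x$status == "crossover_found") {
    cat(sprintf("; delta_s_co = %.4f mm (bracket %.2f-%.2f)",
                x$delta_s_co, x$bracket[1], x$bracket[2]))
  }
  if (is.finite(x$plateau_offset)) {
    cat(sprintf("; plateau at %.2f mm", x$plateau_offset))
  }
  cat("\n")
  invisible(x)
}

#' Detectability-limit offset from the bottom-material SAM curve
#'
#' Detectability of the Raman-active materials is lost roughly where the
#' bottom-material SAM plateaus and turns over. The curve is smoothed by a
#' centered moving average and the offset of its maximum is returned,
#' provided the maximum is interior and the subsequent decrease exceeds a
#' noise guard of twice the MAD of the curve's increments. Returns NA when
#' the smoothed curve is still rising at the last offset.
#'
#' @param curve a `sam_curve`.
#' @param smooth_window odd moving-average window (default 5).
#' @return Offset of the plateau/turnover, mm, or NA.
#' @export
find_detectability_limit <- function(curve, smooth_window = 5L) {
  if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
  ok <- is.finite(curve$sam_bottom)
  cv <- curve[ok, , drop = FALSE]
  y <- cv$sam_bottom
  n <- length(y)
  if (n < 3) return(NA_real_)
  if (smooth_window > 1 && n >= smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(y, k, sides = 2)
    half <- (smooth_window - 1) / 2
    sm[seq_len(half)] <- y[seq_len(half)]
    sm[(n - half + 1):n] <- y[(n - half + 1):n]
    y <- as.numeric(sm)
  }
  i_max <- which.max(y)
  if (i_max == 1 || i_max == n) return(NA_real_)
  guard <- 2 * mad(diff(y))
  drop_after <- y[i_max] - min(y[i_max:n])
  if (drop_after <= guard) return(NA_real_)
  cv$offset[i_max]
}

#' Write a SAM curve and crossover summary to disk
#'
#' @param curve a `sam_curve`.
#' @param crossover a `crossover_result` (optional).
#' @param path_csv CSV output path for the curve.
#' @param path_json JSON output path for the summary (optional).
#' @return Invisibly, the paths written.
#' @export
write_sam_curve <- function(curve, crossover = NULL, path_csv,
                            path_json = NULL) {
  write.csv(as.data.frame(curve), path_csv, row.names = FALSE)
  if (!is.null(path_json) && !is.null(crossover)) {
    jsonlite::write_json(list(status = crossover$status,
                              delta_s_co = crossover$delta_s_co,
                              bracket = crossover$bracket,
                              plateau_offset = crossover$plateau_offset),
                         path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(path_csv, path_json))
}

#' Plot a SAM curve
#'
#' @param x a `sam_curve`.
#' @param crossover optional `crossover_result` to mark.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.sam_curve <- function(x, crossover = NULL, ...) {
  graphics::matplot(x$offset, cbind(x$sam_top, x$sam_bottom, x$sam_total),
                    type = "b", pch = c(1, 2, 3), lty = c(1, 1, 3),
                    xlab = "spatial offset (mm)", ylab = "SAM", ...)
  graphics::legend("topright", c("top", "bottom", "total"),
                   pch = c(1, 2, 3), lty = c(1, 1, 3), col = 1:3, bty = "n")
  if (!is.null(crossover) && crossover$status == "crossover_found") {
    graphics::abline(v = crossover$delta_s_co, lty = 2)
  }
  invisible(x)
}
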