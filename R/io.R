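#' Write a SORS cube as multi-page TIFFs with a JSON sidecar
#'
#' One multi-page TIFF per offset (page = spatial row, each a 1 x channels
#' strip), intensities scaled into `[0, 1]` by the cube's maximum; the
#' scale, offsets, configuration, stages and any ground-truth fractions go
#' to `sidecar.json`.
#'
#' @param cube a `sors_cube`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sors_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "sors_cube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(cube$data)
  top <- max(cube$data, 1e-12)
  lo <- min(cube$data, 0)
  scale <- top - lo
  for (i in seq_len(d[1])) {
    pages <- lapply(seq_len(d[2]), function(j) {
      matrix((cube$data[i, j, ] - lo) / scale, nrow = 1)
    })
    tiff::writeTIFF(pages, file.path(dir, sprintf("frame_%03d.tiff", i - 1)),
                    bits.per.sample = 32L)
  }
  meta <- cube$meta
  side <- list(n_offsets = d[1], n_line_positions = d[2], n_channels = d[3],
               offsets = cube$offsets, wavenumber = cube$wavenumber,
               intensity_scale = scale, intensity_offset = lo,
               stages = meta$stages, snv = isTRUE(meta$snv),
               phantom = unclass(meta$phantom),
               acq = unclass(meta$acq),
               noise = unclass(meta$noise),
               fractions = if (!is.null(meta$fractions)) {
                 as.data.frame(meta$fractions)
               })
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a SORS cube written by [write_sors_cube()]
#'
#' @param dir directory holding `frame_*.tiff` and `sidecar.json`.
#' @return A `sors_cube`.
#' @export
read_sors_cube <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  n_off <- side$n_offsets; n_row <- side$n_line_positions
  n_ch <- side$n_channels
  cube <- array(0, dim = c(n_off, n_row, n_ch))
  for (i in seq_len(n_off)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("frame_%03d.tiff", i - 1)),
                            all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (j in seq_len(n_row)) {
      cube[i, j, ] <- as.numeric(pages[[j]]) * side$intensity_scale +
        side$intensity_offset
    }
  }
  meta <- list(stages = side$stages, snv = isTRUE(side$snv))
  if (!is.null(side$phantom)) {
    meta$phantom <- do.call(phantom_spec, side$phantom[c("recipe_name",
                                                         "thickness_t",
                                                         "mu_a", "mu_s_prime")])
  }
  if (!is.null(side$acq)) {
    meta$acq <- do.call(acquisition_config,
                        side$acq[intersect(names(side$acq),
                                           names(formals(acquisition_config)))])
  }
  if (!is.null(side$fractions)) {
    fr <- side$fractions
    meta$fractions <- offset_fraction_table(fr$offset, fr$fraction_bottom,
                                            fr$total_weight)
  }
  wn <- unlist(side$wavenumber)
  if (!is.numeric(wn) || length(wn) == 0) wn <- NULL
  structure(list(data = cube, offsets = side$offsets,
                 wavenumber = wn, meta = meta),
            class = "sors_cube")
}

#' Per-offset mean spectra of a cube as CSV
#'
#' @param cube a `sors_cube`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_mean_spectra_csv <- function(cube, path) {
  d <- dim(cube$data)
  m <- t(vapply(seq_len(d[1]),
                function(i) colMeans(matrix(cube$data[i, , ], nrow = d[2])),
                numeric(d[3])))
  df <- data.frame(offset = cube$offsets, m)
  names(df)[-1] <- if (!is.null(cube$wavenumber)) {
    sprintf("wn_%.1f", cube$wavenumber)
  } else sprintf("ch_%d", seq_len(d[3]) - 1)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
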