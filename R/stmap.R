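#' Build the rPPG spatio-temporal map of a window
#'
#' Per frame, the axis-aligned bounding box of all landmarks is divided into a
#' `grid_rows x grid_cols` grid of ROIs; each cell's mean R, G, B value forms
#' one sample of that cell's color time series.  Each (channel, cell) series is
#' then min-max normalized over the window, so blood-volume-pulse oscillations
#' occupy the full `[0, 1]` range regardless of their raw amplitude; a
#' degenerate series (max equal to min) maps to the constant 0.5.
#'
#' Rows are ordered row-major over `(grid_row, grid_col)`; channels R, G, B.
#'
#' @param window a `"video_window"`.
#' @param grid_rows,grid_cols facial grid size (default 5 x 5, H = 25 ROIs).
#' @return object of class `"stmap"`: list with `values` `(3, H, L)` in
#'   `[0, 1]`, `H`, `fps`, `grid_rows`, `grid_cols`.
#' @export
build_stmap <- function(window, grid_rows = 5L, grid_cols = 5L) {
  stopifnot(inherits(window, "video_window"))
  d <- dim(window$frames)
  h <- d[1]; w <- d[2]; L <- d[4]
  H <- grid_rows * grid_cols
  raw <- array(0, c(3, H, L))
  for (t in seq_len(L)) {
    lm <- window$landmarks[t, , ]
    x0 <- max(1, floor(min(lm[, 1]))); x1 <- min(w, ceiling(max(lm[, 1])))
    y0 <- max(1, floor(min(lm[, 2]))); y1 <- min(h, ceiling(max(lm[, 2])))
    if (x1 <= x0 || y1 <= y0) stop("empty landmark bounding box")
    xs <- round(seq(x0, x1, length.out = grid_cols + 1))
    ys <- round(seq(y0, y1, length.out = grid_rows + 1))
    for (gr in seq_len(grid_rows)) {
      rr <- ys[gr]:max(ys[gr + 1] - 1, ys[gr])
      for (gc in seq_len(grid_cols)) {
        cc <- xs[gc]:max(xs[gc + 1] - 1, xs[gc])
        cell <- (gr - 1L) * grid_cols + gc
        for (ch in 1:3)
          raw[ch, cell, t] <- mean(window$frames[rr, cc, ch, t])
      }
    }
  }
  values <- normalize_stmap_rows(raw)
  structure(list(values = values, H = H, fps = window$fps,
                 grid_rows = grid_rows, grid_cols = grid_cols),
            class = "stmap")
}

# min-max normalize each (channel, row) series over time; degenerate -> 0.5
normalize_stmap_rows <- function(raw) {
  d <- dim(raw)
  out <- raw
  for (ch in seq_len(d[1])) for (cell in seq_len(d[2])) {
    v <- raw[ch, cell, ]
    rng <- range(v)
    if (rng[2] > rng[1]) out[ch, cell, ] <- (v - rng[1]) / (rng[2] - rng[1])
    else out[ch, cell, ] <- 0.5
  }
  out
}

#' Read a periodic rate from an STMap by Fourier analysis
#'
#' Test oracle: averages the band-limited power spectra of the green-channel
#' rows and returns 60 times the peak frequency (cycles/min), plus a
#' peak-to-median power ratio as confidence.  This reads heart or respiration
#' rate directly from the map without any learned model, which makes it an
#' independent check on both the synthetic generator and the STMap
#' construction.
#'
#' @param stmap an `"stmap"` object.
#' @param band `(low, high)` frequency band in Hz, within `(0, fps/2)`.
#' @param channel channel index to analyse (2 = green).
#' @param pad_factor zero-padding factor refining the frequency grid.
#' @return list with `rate` (cycles/min, `NA` when undefined), `freq_hz`,
#'   `confidence` (peak power / median band power; 0 for a flat map),
#'   `undefined` flag and `bin_bpm`, the nominal FFT bin width in cycles/min.
#' @export
oracle_rate_from_stmap <- function(stmap, band = c(0.7, 3), channel = 2L,
                                   pad_factor = 4L) {
  stopifnot(inherits(stmap, "stmap"))
  v <- stmap$values[channel, , , drop = FALSE]
  H <- dim(v)[2]; L <- dim(v)[3]
  fps <- stmap$fps
  if (band[1] <= 0 || band[2] >= fps / 2 || band[2] <= band[1])
    stop("`band` must lie within (0, fps/2)")
  n <- L * pad_factor
  freqs <- (0:(n %/% 2)) * fps / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("band empty after discretization")
  rows <- matrix(v[1, , ], H, L)
  rows <- rows - rowMeans(rows)
  if (all(abs(rows) < 1e-12))
    return(list(rate = NA_real_, freq_hz = NA_real_, confidence = 0,
                undefined = TRUE, bin_bpm = 60 * fps / L))
  pow <- numeric(sum(in_band))
  for (i in seq_len(H)) {
    x <- c(rows[i, ], rep(0, n - L))
    sp <- Mod(fft(x)[seq_along(freqs)])^2
    pow <- pow + sp[in_band]
  }
  pow <- pow / H
  peak <- which.max(pow)
  conf <- pow[peak] / max(median(pow), .Machine$double.eps)
  list(rate = 60 * freqs[in_band][peak], freq_hz = freqs[in_band][peak],
       confidence = conf, undefined = FALSE, bin_bpm = 60 * fps / L)
}
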