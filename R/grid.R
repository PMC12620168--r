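#' Acquisition grid for an MRS experiment
#'
#' An acquisition grid fixes the sampling of the free induction decay (FID)
#' and the frequency axis of its spectrum: the number of complex time points,
#' the sampling bandwidth, the spectrometer (transmitter) frequency used for
#' the Hz/ppm conversion, and the chemical shift sitting at zero frequency
#' offset (the carrier, conventionally the water resonance at 4.7 ppm).
#'
#' The time axis is `t_i = i / bandwidth_hz`, `i = 0..n_points - 1`. The
#' frequency axis (after the FFT reordering applied by [to_spectrum()]) is
#' ascending from `-bandwidth_hz/2` to `bandwidth_hz/2 - df` in offset Hz,
#' i.e. `carrier_ppm - bw/(2 tx)` to just under `carrier_ppm + bw/(2 tx)`
#' in ppm.
#'
#' @param n_points Number of complex samples (default 1024).
#' @param bandwidth_hz Sampling bandwidth in Hz (default 1199).
#' @param transmitter_mhz Spectrometer frequency in MHz, so that
#'   1 ppm = `transmitter_mhz` Hz (default 127.7, a 3 T proton system).
#' @param carrier_ppm Chemical shift at zero frequency offset (default 4.7).
#' @return An object of class `acq_grid`.
#' @examples
#' g <- acq_grid()
#' range(ppm_axis(g))
#' @export
acq_grid <- function(n_points = 1024L, bandwidth_hz = 1199,
                     transmitter_mhz = 127.7, carrier_ppm = 4.7) {
  n_points <- as.integer(n_points)
  stopifnot(length(n_points) == 1L, n_points > 0L,
            length(bandwidth_hz) == 1L, is.finite(bandwidth_hz), bandwidth_hz > 0,
            length(transmitter_mhz) == 1L, is.finite(transmitter_mhz), transmitter_mhz > 0,
            length(carrier_ppm) == 1L, is.finite(carrier_ppm))
  structure(list(n_points = n_points, bandwidth_hz = bandwidth_hz,
                 transmitter_mhz = transmitter_mhz, carrier_ppm = carrier_ppm),
            class = "acq_grid")
}

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf("<acq_grid> %d points, %.6g Hz bandwidth, %.6g MHz, carrier %.6g ppm\n",
              x$n_points, x$bandwidth_hz, x$transmitter_mhz, x$carrier_ppm))
  invisible(x)
}

is_acq_grid <- function(x) inherits(x, "acq_grid")

assert_grid <- function(grid) {
  if (!is_acq_grid(grid)) stop("`grid` must be an `acq_grid` object", call. = FALSE)
  invisible(grid)
}

#' Time axis of an acquisition grid
#'
#' @param grid An [acq_grid()].
#' @return Numeric vector `t_i = i / bandwidth_hz`, length `n_points`.
#' @export
time_axis <- function(grid) {
  assert_grid(grid)
  seq(0L, grid$n_points - 1L) / grid$bandwidth_hz
}

#' Frequency axis (offset Hz) of the reordered spectrum
#'
#' Ascending frequency offsets of the spectrum bins produced by
#' [to_spectrum()] (which reorders the raw FFT output so that negative
#' offsets come first).
#'
#' @inheritParams time_axis
#' @return Numeric vector of frequency offsets in Hz, length `n_points`.
#' @export
freq_axis_hz <- function(grid) {
  assert_grid(grid)
  n <- grid$n_points
  (seq_len(n) - 1L - floor(n / 2)) * grid$bandwidth_hz / n
}

#' Chemical-shift (ppm) axis of the reordered spectrum
#'
#' @inheritParams time_axis
#' @return Numeric vector of ppm values, strictly increasing.
#' @export
ppm_axis <- function(grid) {
  hz_to_ppm(freq_axis_hz(grid), grid)
}

#' Convert chemical shift to frequency offset
#'
#' `ppm_to_hz()` maps a chemical shift in ppm to a frequency offset in Hz
#' relative to the grid carrier; `hz_to_ppm()` is its exact inverse.
#'
#' @param ppm,hz Numeric vectors.
#' @inheritParams time_axis
#' @return Numeric vector of the same length as the input.
#' @export
ppm_to_hz <- function(ppm, grid) {
  assert_grid(grid)
  (ppm - grid$carrier_ppm) * grid$transmitter_mhz
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, grid) {
  assert_grid(grid)
  grid$carrier_ppm + hz / grid$transmitter_mhz
}

#' Select spectrum bins inside a ppm band
#'
#' Returns a logical mask over the (reordered, ascending-ppm) frequency bins
#' selecting those with ppm in the half-open interval `[lo_ppm, hi_ppm)`.
#' The half-open convention makes adjacent bands partition the axis: the
#' masks of `[a, b)` and `[b, c)` are disjoint and their union is the mask
#' of `[a, c)`. An empty band yields an all-`FALSE` mask, not an error.
#'
#' @inheritParams time_axis
#' @param lo_ppm,hi_ppm Band edges in ppm, `lo_ppm < hi_ppm`.
#' @return Logical vector of length `n_points`.
#' @export
band_mask <- function(grid, lo_ppm, hi_ppm) {
  assert_grid(grid)
  stopifnot(is.finite(lo_ppm), lo_ppm < hi_ppm)
  ppm <- ppm_axis(grid)
  ppm >= lo_ppm & ppm < hi_ppm
}

# fftshift/ifftshift index permutations (internal). For even n they agree.
fftshift_idx <- function(n) c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
ifftshift_idx <- function(n) c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))
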