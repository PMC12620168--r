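#' FID and spectrum containers
#'
#' `fid_signal()` wraps a complex time-domain signal together with its
#' [acq_grid()]; `mrs_spectrum()` does the same for a frequency-domain
#' spectrum (real part = absorption, imaginary part = dispersion) on the
#' ascending-ppm axis.
#'
#' @param samples,values Complex (or numeric) vector of length
#'   `grid$n_points`; non-finite values are rejected.
#' @param grid An [acq_grid()].
#' @return An object of class `fid_signal` / `mrs_spectrum` with fields
#'   `samples` / `values` and `grid`.
#' @export
fid_signal <- function(samples, grid) {
  assert_grid(grid)
  samples <- as.complex(samples)
  if (length(samples) != grid$n_points)
    stop("length(samples) must equal grid$n_points", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(Re(samples)) | !is.finite(Im(samples))))
    stop("FID samples must be finite", call. = FALSE)
  structure(list(samples = samples, grid = grid), class = "fid_signal")
}

#' @rdname fid_signal
#' @export
mrs_spectrum <- function(values, grid) {
  assert_grid(grid)
  values <- as.complex(values)
  if (length(values) != grid$n_points)
    stop("length(values) must equal grid$n_points", call. = FALSE)
  if (anyNA(values) || any(!is.finite(Re(values)) | !is.finite(Im(values))))
    stop("spectrum values must be finite", call. = FALSE)
  structure(list(values = values, grid = grid), class = "mrs_spectrum")
}

#' @export
print.fid_signal <- function(x, ...) {
  cat(sprintf("<fid_signal> %d complex samples over %.4g s\n",
              x$grid$n_points, x$grid$n_points / x$grid$bandwidth_hz))
  invisible(x)
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  p <- range(ppm_axis(x$grid))
  cat(sprintf("<mrs_spectrum> %d bins, %.3f to %.3f ppm\n",
              x$grid$n_points, p[1], p[2]))
  invisible(x)
}

#' Fourier transform between FID and spectrum
#'
#' The fixed transform convention of the package: the forward transform is
#' the unscaled discrete Fourier transform of the FID, reordered so that the
#' frequency axis ascends from `-bw/2` (i.e. the bins match [ppm_axis()]);
#' the inverse undoes the reordering and carries the `1/N` factor. The two
#' are mutual inverses to machine precision, and Parseval's identity holds
#' as `sum(|spectrum|^2) = N * sum(|fid|^2)`.
#'
#' @param fid A [fid_signal()].
#' @param spec An [mrs_spectrum()].
#' @return `to_spectrum()` returns an `mrs_spectrum`; `from_spectrum()` a
#'   `fid_signal`.
#' @export
to_spectrum <- function(fid) {
  stopifnot(inherits(fid, "fid_signal"))
  v <- stats::fft(fid$samples)[fftshift_idx(fid$grid$n_points)]
  mrs_spectrum(v, fid$grid)
}

#' @rdname to_spectrum
#' @export
from_spectrum <- function(spec) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  n <- spec$grid$n_points
  s <- stats::fft(spec$values[ifftshift_idx(n)], inverse = TRUE) / n
  fid_signal(s, spec$grid)
}

# Matrix versions used by the batch fitters (columns = spectra), internal.
fft_fwd_mat <- function(M) stats::mvfft(M)[fftshift_idx(nrow(M)), , drop = FALSE]
fft_adj_mat <- function(G) stats::mvfft(G[ifftshift_idx(nrow(G)), , drop = FALSE],
                                        inverse = TRUE)

#' Lorentzian component tables
#'
#' A Lorentzian component is one exponentially damped complex sinusoid,
#' `A * exp(-w t) * exp(i (2 pi f_hz t + phi))`, the shared model unit of
#' the water simulator, the WaterFit model and the HSVD decomposition. A set
#' of components is stored as a data frame with columns `amplitude` (a.u.,
#' non-negative), `damping_hz` (decay rate in the literal exponent, s^-1,
#' non-negative), `freq_ppm` (chemical shift) and `phase` (radians).
#'
#' @param amplitude,damping_hz,freq_ppm,phase Numeric vectors, recycled to a
#'   common length.
#' @return A data frame of class `lorentzian_set`.
#' @examples
#' lorentzian_components(1, 40, 4.7, 0)
#' @export
lorentzian_components <- function(amplitude, damping_hz, freq_ppm, phase = 0) {
  d <- data.frame(amplitude = amplitude, damping_hz = damping_hz,
                  freq_ppm = freq_ppm, phase = phase)
  if (any(!is.finite(as.matrix(d)))) stop("component parameters must be finite", call. = FALSE)
  if (any(d$amplitude < 0)) stop("amplitude must be non-negative", call. = FALSE)
  if (any(d$damping_hz < 0)) stop("damping must be non-negative", call. = FALSE)
  class(d) <- c("lorentzian_set", "data.frame")
  d
}

#' Evaluate a sum of Lorentzian components as a time-domain FID
#'
#' Evaluates `sum_j A_j exp(-w_j t) exp(i (2 pi f_j t + phi_j))` on the
#' grid's time axis, with `f_j` in Hz derived from `freq_ppm` through the
#' grid. Linear in the amplitudes; negative dampings are rejected.
#'
#' @param components A [lorentzian_components()] table (or a data frame with
#'   the same columns).
#' @param grid An [acq_grid()].
#' @return A [fid_signal()].
#' @export
lorentzian_fid <- function(components, grid) {
  assert_grid(grid)
  stopifnot(is.data.frame(components))
  if (nrow(components) == 0L)
    return(fid_signal(complex(grid$n_points), grid))
  if (any(components$damping_hz < 0))
    stop("damping must be non-negative", call. = FALSE)
  t <- time_axis(grid)
  f_hz <- ppm_to_hz(components$freq_ppm, grid)
  E <- exp(outer(t, complex(real = -components$damping_hz, imaginary = 2 * pi * f_hz)))
  coeff <- components$amplitude * exp(1i * components$phase)
  fid_signal(as.vector(E %*% coeff), grid)
}
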