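#' HSVD configuration
#'
#' Settings of the Hankel-SVD comparator: the Hankel matrix size (512 x 512
#' by default, consuming samples `0..1022` of a 1024-point FID), the number
#' of retained singular values (model order, default 30) and the ppm band
#' whose components count as water.
#'
#' @param hankel_rows,hankel_cols Hankel matrix dimensions; must satisfy
#'   `rows + cols - 1 <= n_points` of the processed FID.
#' @param n_singular_values Retained model order, `<= min(rows, cols)`.
#' @param water_band_ppm Half-open ppm band of components to subtract.
#' @param growing_poles Handling of poles with `|z| > 1` (negative damping):
#'   `"clamp"` (default) projects them onto the unit circle so the reported
#'   damping is 0; `"drop"` discards them.
#' @return A list of class `hsvd_config`.
#' @export
hsvd_config <- function(hankel_rows = 512L, hankel_cols = 512L,
                        n_singular_values = 30L,
                        water_band_ppm = c(4.4, 5.0),
                        growing_poles = c("clamp", "drop")) {
  growing_poles <- match.arg(growing_poles)
  stopifnot(hankel_rows >= 2L, hankel_cols >= 2L,
            n_singular_values >= 1L,
            n_singular_values <= min(hankel_rows, hankel_cols),
            length(water_band_ppm) == 2L, diff(water_band_ppm) > 0)
  structure(list(hankel_rows = as.integer(hankel_rows),
                 hankel_cols = as.integer(hankel_cols),
                 n_singular_values = as.integer(n_singular_values),
                 water_band_ppm = water_band_ppm,
                 growing_poles = growing_poles),
            class = "hsvd_config")
}

#' Build a Hankel matrix from an FID
#'
#' Entry `(i, j)` is `samples[i + j - 1]` (1-based), so anti-diagonals are
#' constant and a `rows x cols` matrix consumes samples
#' `1..(rows + cols - 1)`.
#'
#' @param fid A [fid_signal()] or a complex vector.
#' @param rows,cols Matrix dimensions; `rows + cols - 1` must not exceed the
#'   signal length.
#' @return A `rows x cols` complex matrix.
#' @export
build_hankel <- function(fid, rows, cols) {
  x <- if (inherits(fid, "fid_signal")) fid$samples else as.complex(fid)
  if (rows + cols - 1L > length(x))
    stop("rows + cols - 1 exceeds the FID length", call. = FALSE)
  matrix(x[outer(seq_len(rows), seq_len(cols), `+`) - 1L], rows, cols)
}

#' Decompose an FID into exponentially damped sinusoids
#'
#' Classical state-space HSVD: truncated SVD of the Hankel matrix of the
#' FID, a shift-invariance least-squares solve on the retained left singular
#' vectors for the signal poles, and a linear least-squares fit of the
#' complex amplitudes against the full FID. Each pole
#' `z = exp((-w + i 2 pi f) dt)` yields one Lorentzian component; growing
#' poles (`|z| > 1`) are clamped to the unit circle (zero damping) or
#' dropped according to the configuration, never kept as growing
#' exponentials.
#'
#' @param fid A [fid_signal()].
#' @param cfg An [hsvd_config()].
#' @return A [lorentzian_components()] table (one row per retained
#'   component), with the pole moduli-clamping applied before the amplitude
#'   fit so that the reported components reproduce the returned model.
#' @export
hsvd_decompose <- function(fid, cfg = hsvd_config()) {
  stopifnot(inherits(fid, "fid_signal"), inherits(cfg, "hsvd_config"))
  grid <- fid$grid
  if (cfg$hankel_rows + cfg$hankel_cols - 1L > grid$n_points)
    stop("Hankel matrix too large for this FID", call. = FALSE)
  H <- build_hankel(fid, cfg$hankel_rows, cfg$hankel_cols)
  K <- cfg$n_singular_values
  sv <- svd(H, nu = K, nv = 0)
  # discard numerically null directions (pure zero signal etc.)
  keep <- sv$d[seq_len(K)] > max(sv$d[1], .Machine$double.eps) * 1e-12
  U <- sv$u[, keep, drop = FALSE]
  if (ncol(U) == 0L)
    return(lorentzian_components(numeric(0), numeric(0), numeric(0), numeric(0)))
  U1 <- U[-nrow(U), , drop = FALSE]
  U2 <- U[-1L, , drop = FALSE]
  ct <- Conj(t(U1))
  Z <- solve(ct %*% U1, ct %*% U2)
  z <- eigen(Z, only.values = TRUE)$values
  if (cfg$growing_poles == "drop") z <- z[Mod(z) <= 1]
  else z <- ifelse(Mod(z) > 1, z / Mod(z), z)
  z <- z[Mod(z) > 0]
  if (length(z) == 0L)
    return(lorentzian_components(numeric(0), numeric(0), numeric(0), numeric(0)))
  dt <- 1 / grid$bandwidth_hz
  damping <- pmax(-log(Mod(z)) / dt, 0)
  f_hz <- Arg(z) / (2 * pi * dt)
  V <- exp(outer(0:(grid$n_points - 1L), log(z)))   # Vandermonde z^n
  a <- qr.coef(qr(V), fid$samples)
  ok <- is.finite(Mod(a)) & Mod(a) > 0
  lorentzian_components(Mod(a[ok]), damping[ok], hz_to_ppm(f_hz[ok], grid),
                        Arg(a[ok]))
}

#' Remove water by HSVD band selection
#'
#' Decomposes the FID with [hsvd_decompose()], sums the components whose
#' frequency falls inside the water band (half-open, like [band_mask()])
#' into a water-only FID, and subtracts it.
#'
#' @inheritParams hsvd_decompose
#' @return An `hsvd_result`: list with `components` (all retained),
#'   `water_components` (in-band subset), `water_fid`, `cleaned_fid`
#'   (`input - water_fid`, exactly).
#' @export
remove_water_hsvd <- function(fid, cfg = hsvd_config()) {
  comp <- hsvd_decompose(fid, cfg)
  inband <- comp$freq_ppm >= cfg$water_band_ppm[1] &
    comp$freq_ppm < cfg$water_band_ppm[2]
  water <- comp[inband, , drop = FALSE]
  wfid <- lorentzian_fid(water, fid$grid)
  structure(list(components = comp, water_components = water,
                 water_fid = wfid,
                 cleaned_fid = fid_signal(fid$samples - wfid$samples, fid$grid)),
            class = "hsvd_result")
}

#' @export
print.hsvd_result <- function(x, ...) {
  cat(sprintf("<hsvd_result> %d components, %d in water band\n",
              nrow(x$components), nrow(x$water_components)))
  invisible(x)
}
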