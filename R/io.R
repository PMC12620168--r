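#' Read and write a single FID as CSV
#'
#' Plain-text exchange format for one spectrum: a two-column CSV
#' (`real`, `imag`) of the time-domain samples. The acquisition grid is not
#' stored in the CSV; supply it on read (vendor raw formats are a
#' documented extension point, not implemented).
#'
#' @param fid A [fid_signal()].
#' @param path File path.
#' @param grid An [acq_grid()] describing the samples being read.
#' @return `write_fid_csv()` returns `path` invisibly; `read_fid_csv()` a
#'   [fid_signal()].
#' @export
write_fid_csv <- function(fid, path) {
  stopifnot(inherits(fid, "fid_signal"))
  utils::write.csv(data.frame(real = Re(fid$samples), imag = Im(fid$samples)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fid_csv
#' @export
read_fid_csv <- function(path, grid) {
  d <- utils::read.csv(path)
  stopifnot(all(c("real", "imag") %in% names(d)))
  fid_signal(complex(real = d$real, imaginary = d$imag), grid)
}

#' Read and write a simulated dataset container
#'
#' JSON container for a [simulate_dataset()] result: the acquisition grid,
#' and per record the observed FID, the noise-free water FID, the
#' ground-truth amplitudes and the noise level. (A plain-text stand-in for
#' a binary spectrum container; numbers are stored at full precision.)
#'
#' @param dataset A `sim_dataset`.
#' @param path File path (`.json`).
#' @return `write_sim_dataset()` returns `path` invisibly;
#'   `read_sim_dataset()` a list of `sim_record`-like lists of class
#'   `sim_dataset`.
#' @export
write_sim_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sim_dataset"))
  g <- attr(dataset, "config")$grid
  obj <- list(
    grid = list(n_points = g$n_points, bandwidth_hz = g$bandwidth_hz,
                transmitter_mhz = g$transmitter_mhz, carrier_ppm = g$carrier_ppm),
    records = lapply(dataset, function(r) list(
      fid_re = Re(r$fid$samples), fid_im = Im(r$fid$samples),
      water_re = Re(r$water_truth$samples), water_im = Im(r$water_truth$samples),
      truth_amplitudes = as.list(r$truth_amplitudes),
      snr = r$snr, noise_sd = r$noise_sd)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_dataset
#' @export
read_sim_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  g <- acq_grid(obj$grid$n_points, obj$grid$bandwidth_hz,
                obj$grid$transmitter_mhz, obj$grid$carrier_ppm)
  records <- lapply(obj$records, function(r) {
    structure(list(
      fid = fid_signal(complex(real = r$fid_re, imaginary = r$fid_im), g),
      water_truth = fid_signal(complex(real = r$water_re, imaginary = r$water_im), g),
      truth_amplitudes = unlist(r$truth_amplitudes),
      snr = if (is.null(r$snr)) NA_real_ else r$snr,
      noise_sd = r$noise_sd), class = "sim_record")
  })
  structure(records, class = "sim_dataset",
            config = list(grid = g, seed = NA_integer_))
}
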