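#' Default metabolite basis definitions
#'
#' Nine brain metabolites with base amplitudes (arbitrary units) and
#' Lorentzian line lists at literature chemical shifts. Each metabolite is a
#' list with `name`, `base_amplitude` and `lines` (data frame of `shift_ppm`
#' and `weight`; weights sum to 1 and all lines lie in the 0.4-4.4 ppm
#' metabolite region). The same line lists serve as the simulation ground
#' truth and as the quantification basis, so the benchmark is
#' self-consistent. Multi-line patterns are weighted by approximate proton
#' ratios (e.g. creatine CH3 vs CH2 as 0.6/0.4).
#'
#' @return Named list of nine metabolite definitions.
#' @examples
#' names(metabolite_definitions())
#' @export
metabolite_definitions <- function() {
  def <- function(name, base, shifts, weights = rep(1 / length(shifts), length(shifts))) {
    stopifnot(abs(sum(weights) - 1) < 1e-12, all(shifts >= 0.4 & shifts <= 4.4))
    list(name = name, base_amplitude = base,
         lines = data.frame(shift_ppm = shifts, weight = weights))
  }
  out <- list(
    def("NAA",         1.12, 2.01),
    def("Cho",         8.83, 3.19),
    def("Cr",          1.33, c(3.03, 3.91), c(0.6, 0.4)),
    def("Gln",         1.12, c(2.45, 3.77)),
    def("NAA_2.6ppm",  5.46, 2.60),
    def("Lac",         0.83, 1.31),
    def("mI",          1.71, c(3.52, 3.61)),
    def("Glu",         0.43, c(2.35, 3.75)),
    def("Asp",         5.93, c(2.68, 2.80))
  )
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Water residual simulation configuration
#'
#' Five Lorentzian water peaks with baseline parameters (amplitudes
#' `{1, 0.33, 0.33, 0.11, 0.11}` a.u., damping 40 Hz, shifts
#' `{4.7, 4.78, 4.62, 4.85, 4.55}` ppm, phase 0) randomized per spectrum:
#' amplitude `A0 * U(10, 150)`, damping `w0 * U(0.3, 1.7)`, shift
#' `f0 + shift_sd_ppm * N(0, 1)` ppm, phase `N(0, phase_sd_rad)` rad.
#' Collapsing a range (e.g. `amp_factor_range = c(0, 0)`) makes the draw
#' deterministic.
#'
#' @param peaks Data frame with columns `A0`, `w0_hz`, `f0_ppm`, `phi0`.
#' @param amp_factor_range,damping_factor_range Uniform supports for the
#'   multiplicative amplitude and damping factors.
#' @param shift_sd_ppm,phase_sd_rad Gaussian SDs of the shift (ppm) and
#'   phase (rad) perturbations.
#' @return A list of class `water_sim_config`.
#' @export
water_sim_config <- function(peaks = data.frame(A0 = c(1, 0.33, 0.33, 0.11, 0.11),
                                                w0_hz = 40,
                                                f0_ppm = c(4.7, 4.78, 4.62, 4.85, 4.55),
                                                phi0 = 0),
                             amp_factor_range = c(10, 150),
                             damping_factor_range = c(0.3, 1.7),
                             shift_sd_ppm = 0.1,
                             phase_sd_rad = pi) {
  stopifnot(all(c("A0", "w0_hz", "f0_ppm", "phi0") %in% names(peaks)),
            length(amp_factor_range) == 2L, diff(amp_factor_range) >= 0,
            length(damping_factor_range) == 2L, diff(damping_factor_range) >= 0,
            shift_sd_ppm >= 0, phase_sd_rad >= 0)
  structure(list(peaks = peaks, amp_factor_range = amp_factor_range,
                 damping_factor_range = damping_factor_range,
                 shift_sd_ppm = shift_sd_ppm, phase_sd_rad = phase_sd_rad),
            class = "water_sim_config")
}

#' Simulation configuration
#'
#' The stated world of the synthetic benchmark: nine metabolites with base
#' amplitudes scaled per metabolite by `U(0.1, 2)`, a common (per-spectrum)
#' frequency shift `U(-20, 20)` Hz, damping `U(1.5, 6)` Hz and phase
#' `U(-pi/4, pi/4)` rad (set `per_metabolite = TRUE` to draw those three per
#' metabolite instead), a five-Lorentzian water residual per
#' [water_sim_config()], and circular complex Gaussian noise at an SNR drawn
#' uniformly from `snr_range`.
#'
#' SNR convention: the reference level is the maximum magnitude of the
#' noise-free spectrum of the reference signal divided by the
#' frequency-domain per-component noise SD. `snr_reference = "naa"`
#' (default) references the NAA resonance, the field's customary SNR anchor;
#' `"max"` references the full noise-free metabolite spectrum maximum.
#'
#' @param metabolites Named list of metabolite definitions
#'   ([metabolite_definitions()] by default).
#' @param shift_range_hz,damping_range_hz,phase_range_rad,amp_scale_range,snr_range
#'   Two-element uniform supports.
#' @param per_metabolite Draw shift/damping/phase per metabolite (`TRUE`) or
#'   once per spectrum (`FALSE`, default).
#' @param snr_reference `"naa"` or `"max"` (see Details).
#' @param water A [water_sim_config()], or `NULL` to disable the water
#'   residual.
#' @param noise If `FALSE`, no noise is added.
#' @param grid An [acq_grid()].
#' @param seed Integer RNG seed used by [simulate_dataset()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(metabolites = metabolite_definitions(),
                       shift_range_hz = c(-20, 20),
                       damping_range_hz = c(1.5, 6),
                       phase_range_rad = c(-pi / 4, pi / 4),
                       amp_scale_range = c(0.1, 2),
                       snr_range = c(5, 50),
                       per_metabolite = FALSE,
                       snr_reference = c("naa", "max"),
                       water = water_sim_config(),
                       noise = TRUE,
                       grid = acq_grid(),
                       seed = 1L) {
  snr_reference <- match.arg(snr_reference)
  assert_grid(grid)
  rng <- function(r) length(r) == 2L && r[1] <= r[2]
  stopifnot(rng(shift_range_hz), rng(damping_range_hz), rng(phase_range_rad),
            rng(amp_scale_range), rng(snr_range), snr_range[1] > 0)
  if (!is.null(water)) stopifnot(inherits(water, "water_sim_config"))
  structure(list(metabolites = metabolites, shift_range_hz = shift_range_hz,
                 damping_range_hz = damping_range_hz,
                 phase_range_rad = phase_range_rad,
                 amp_scale_range = amp_scale_range, snr_range = snr_range,
                 per_metabolite = per_metabolite, snr_reference = snr_reference,
                 water = water, noise = noise, grid = grid,
                 seed = as.integer(seed)),
            class = "sim_config")
}

runif1 <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
runifn <- function(n, r) if (r[1] == r[2]) rep(r[1], n) else stats::runif(n, r[1], r[2])

#' Simulate the metabolite part of a spectrum
#'
#' Draws per-metabolite amplitude scales from `U(amp_scale_range)` (so the
#' effective amplitude is `base_amplitude * scale`), plus frequency shift,
#' damping and phase from their uniform supports (per spectrum or per
#' metabolite according to the configuration), and evaluates the summed
#' Lorentzian FID of all metabolite lines.
#'
#' @param config A [sim_config()].
#' @return List with `fid` ([fid_signal()]), `truth_amplitudes` (named
#'   vector), `components` (the realized [lorentzian_components()] table)
#'   and `params` (drawn shift/damping/phase).
#' @export
simulate_metabolites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mets <- config$metabolites
  nm <- length(mets)
  scales <- runifn(nm, config$amp_scale_range)
  if (config$per_metabolite) {
    shift <- runifn(nm, config$shift_range_hz)
    damp <- runifn(nm, config$damping_range_hz)
    phase <- runifn(nm, config$phase_range_rad)
  } else {
    shift <- rep(runif1(config$shift_range_hz), nm)
    damp <- rep(runif1(config$damping_range_hz), nm)
    phase <- rep(runif1(config$phase_range_rad), nm)
  }
  truth <- vapply(mets, `[[`, 0, "base_amplitude") * scales
  names(truth) <- names(mets)
  comp <- do.call(rbind, lapply(seq_len(nm), function(i) {
    ln <- mets[[i]]$lines
    data.frame(amplitude = truth[i] * ln$weight,
               damping_hz = damp[i],
               freq_ppm = ln$shift_ppm + shift[i] / config$grid$transmitter_mhz,
               phase = phase[i])
  }))
  class(comp) <- c("lorentzian_set", "data.frame")
  list(fid = lorentzian_fid(comp, config$grid), truth_amplitudes = truth,
       components = comp,
       params = list(scale = scales, shift_hz = shift, damping_hz = damp,
                     phase = phase))
}

#' Simulate the five-Lorentzian water residual
#'
#' Draws each peak's amplitude `A0 * U(10, 150)`, damping `w0 * U(0.3, 1.7)`
#' Hz, shift `f0 + 0.1 N(0,1)` ppm and phase `N(0, pi)` rad (defaults), and
#' returns the summed Lorentzian FID.
#'
#' @param config A [water_sim_config()].
#' @param grid An [acq_grid()].
#' @return List with `fid` and `components`.
#' @export
simulate_water <- function(config, grid) {
  stopifnot(inherits(config, "water_sim_config"))
  assert_grid(grid)
  p <- config$peaks
  k <- nrow(p)
  comp <- lorentzian_components(
    amplitude = p$A0 * runifn(k, config$amp_factor_range),
    damping_hz = p$w0_hz * runifn(k, config$damping_factor_range),
    freq_ppm = p$f0_ppm + config$shift_sd_ppm *
      (if (config$shift_sd_ppm > 0) stats::rnorm(k) else 0),
    phase = p$phi0 + (if (config$phase_sd_rad > 0)
      stats::rnorm(k, 0, config$phase_sd_rad) else 0))
  list(fid = lorentzian_fid(comp, grid), components = comp)
}

#' Add complex Gaussian noise at a target SNR
#'
#' Adds i.i.d. circular complex Gaussian noise in the time domain. The
#' time-domain per-component SD is chosen so that the frequency-domain
#' per-component noise SD equals `reference_level / snr` under the package
#' FFT convention (`sd_freq = sd_time * sqrt(N)`).
#'
#' @param fid A [fid_signal()] to contaminate.
#' @param snr Target signal-to-noise ratio (> 0).
#' @param reference_level Peak magnitude of the noise-free reference
#'   spectrum (must be > 0; see [snr_reference_level()]).
#' @return List with `fid` (noisy) and `noise_sd` (time-domain per-component
#'   SD actually used).
#' @export
add_noise <- function(fid, snr, reference_level) {
  stopifnot(inherits(fid, "fid_signal"), snr > 0)
  if (!is.finite(reference_level) || reference_level <= 0)
    stop("SNR undefined: reference level must be positive", call. = FALSE)
  n <- fid$grid$n_points
  sd_t <- reference_level / snr / sqrt(n)
  noise <- complex(real = stats::rnorm(n, 0, sd_t),
                   imaginary = stats::rnorm(n, 0, sd_t))
  list(fid = fid_signal(fid$samples + noise, fid$grid), noise_sd = sd_t)
}

#' SNR reference level of a simulated metabolite signal
#'
#' Computes the peak magnitude used as SNR numerator: either the maximum of
#' the noise-free NAA-only spectrum (`"naa"`) or of the full noise-free
#' metabolite spectrum (`"max"`).
#'
#' @param metab The output of [simulate_metabolites()].
#' @param config The [sim_config()] that produced it.
#' @return A positive scalar.
#' @export
snr_reference_level <- function(metab, config) {
  if (config$snr_reference == "naa") {
    # rebuild the NAA-only component set from this record's realized draws
    naa <- config$metabolites[["NAA"]]
    i <- match("NAA", names(config$metabolites))
    comp <- data.frame(
      amplitude = metab$truth_amplitudes[["NAA"]] * naa$lines$weight,
      damping_hz = metab$params$damping_hz[i],
      freq_ppm = naa$lines$shift_ppm + metab$params$shift_hz[i] / config$grid$transmitter_mhz,
      phase = metab$params$phase[i])
    max(Mod(to_spectrum(lorentzian_fid(comp, config$grid))$values))
  } else {
    max(Mod(to_spectrum(metab$fid)$values))
  }
}

#' Simulate one spectrum record
#'
#' One draw of the stated world: metabolites + water residual + noise.
#' Consumes the current RNG stream; use [simulate_dataset()] for seeded,
#' reproducible batches.
#'
#' @param config A [sim_config()].
#' @return A `sim_record`: list with `fid` (observed), `metab_fid` and
#'   `water_truth` (noise-free parts), `truth_amplitudes`, `water_components`,
#'   `snr`, `noise_sd`.
#' @export
simulate_record <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  metab <- simulate_metabolites(config)
  if (!is.null(config$water)) {
    water <- simulate_water(config$water, grid)
  } else {
    water <- list(fid = fid_signal(complex(grid$n_points), grid),
                  components = lorentzian_components(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  total <- fid_signal(metab$fid$samples + water$fid$samples, grid)
  snr <- NA_real_
  noise_sd <- 0
  if (isTRUE(config$noise)) {
    snr <- runif1(config$snr_range)
    ref <- snr_reference_level(metab, config)
    noisy <- add_noise(total, snr, ref)
    total <- noisy$fid
    noise_sd <- noisy$noise_sd
  }
  structure(list(fid = total, metab_fid = metab$fid, water_truth = water$fid,
                 truth_amplitudes = metab$truth_amplitudes,
                 metab_params = metab$params,
                 water_components = water$components,
                 snr = snr, noise_sd = noise_sd),
            class = "sim_record")
}

#' Simulate a reproducible dataset
#'
#' Generates `n` independent [simulate_record()] draws. The result is a pure
#' function of `(config, n)`: the RNG is seeded from `config$seed` in a
#' local RNG scope, so repeated calls are bitwise identical and the caller's
#' RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @param n Number of spectra (>= 0).
#' @return A list of `sim_record`s of class `sim_dataset`, with the config
#'   attached as attribute `config`.
#' @export
simulate_dataset <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  records <- with_local_seed(config$seed, {
    lapply(seq_len(n), function(i) simulate_record(config))
  })
  structure(records, class = "sim_dataset", config = config)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d simulated spectra (seed %d)\n",
              length(x), attr(x, "config")$seed))
  invisible(x)
}
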