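# Shared fixtures: grids and reduced simulation configs. Everything is
# generated in code; no stored data.

std_grid <- function() acq_grid()                      # 1024 pt / 1199 Hz / 3 T
toy_grid <- function(n = 64L) acq_grid(n_points = n)   # same axis, fewer bins

# deterministic water draw: all random factors collapsed to fixed values
midpoint_water_config <- function() {
  water_sim_config(amp_factor_range = c(80, 80),
                   damping_factor_range = c(1, 1),
                   shift_sd_ppm = 0, phase_sd_rad = 0)
}

# small, fast configs for optimizer-heavy tests
quick_metab_cfg <- function(...) metab_config(max_iterations = 150L, ...)

# naive O(n^2) DFT matching the package forward convention (independent
# oracle for FFT-dependent expectations)
naive_spectrum <- function(samples) {
  n <- length(samples)
  k_shifted <- c((floor(n / 2)):(n - 1), 0:(floor(n / 2) - 1))  # bin order after reordering
  out <- complex(n)
  for (j in seq_len(n)) {
    k <- k_shifted[j]
    out[j] <- sum(samples * exp(-2i * pi * k * (0:(n - 1)) / n))
  }
  out
}
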