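test_that("metabolite amplitudes scale the tabulated base values", {
  cfg <- sim_config(amp_scale_range = c(1, 1), grid = toy_grid())
  m <- simulate_metabolites(cfg)
  expect_equal(m$truth_amplitudes[["NAA"]], 1.12)
  expect_equal(m$truth_amplitudes[["Cho"]], 8.83)
  expect_equal(unname(m$truth_amplitudes),
               unname(vapply(cfg$metabolites, `[[`, 0, "base_amplitude")))

  zero <- simulate_metabolites(sim_config(amp_scale_range = c(0, 0), grid = toy_grid()))
  expect_true(all(zero$fid$samples == 0))
})

test_that("amplitude scaling follows U(0.1, 2) (Monte Carlo)", {
  cfg <- sim_config(grid = toy_grid())
  set.seed(101)
  naa <- replicate(2000, simulate_metabolites(cfg)$truth_amplitudes[["NAA"]])
  expect_gte(min(naa), 1.12 * 0.1)
  expect_lte(max(naa), 1.12 * 2)
  expect_equal(mean(naa), 1.12 * 1.05, tolerance = 0.05)
})

test_that("water simulation matches the tabulated baseline at collapsed ranges", {
  g <- toy_grid()
  w <- simulate_water(midpoint_water_config(), g)
  expect_equal(w$components$amplitude, 80 * c(1, 0.33, 0.33, 0.11, 0.11))
  expect_equal(w$components$damping_hz, rep(40, 5))
  expect_equal(w$components$freq_ppm, c(4.7, 4.78, 4.62, 4.85, 4.55))
  expect_equal(w$components$phase, rep(0, 5))

  none <- simulate_water(water_sim_config(amp_factor_range = c(0, 0)), g)
  expect_true(all(none$fid$samples == 0))
})

test_that("water damping follows 40 * U(0.3, 1.7) (Monte Carlo)", {
  g <- toy_grid()
  set.seed(202)
  d3 <- replicate(2000, simulate_water(water_sim_config(), g)$components$damping_hz[3])
  expect_gte(min(d3), 12)
  expect_lte(max(d3), 68)
  expect_equal(mean(d3), 40, tolerance = 0.03)
})

test_that("add_noise realizes the requested frequency-domain SD", {
  g <- toy_grid(256)
  base <- fid_signal(rep(1 + 0i, 256), g)
  ref <- 100; snr <- 10
  set.seed(303)
  sds <- replicate(200, {
    out <- add_noise(base, snr, ref)
    noise_spec <- to_spectrum(fid_signal(out$fid$samples - base$samples, g))$values
    stats::sd(c(Re(noise_spec), Im(noise_spec)))
  })
  expect_equal(mean(sds), ref / snr, tolerance = 0.05)

  # noise_sd proportional to the reference level; huge SNR leaves input intact
  a <- add_noise(base, 20, 50)$noise_sd
  b <- add_noise(base, 20, 100)$noise_sd
  expect_equal(b / a, 2, tolerance = 1e-12)
  quiet <- add_noise(base, 1e12, 1)
  expect_lt(max(Mod(quiet$fid$samples - base$samples)), 1e-9)
  expect_error(add_noise(base, 10, 0), "reference")
})

test_that("datasets are pure functions of (config, seed) and decompose exactly", {
  cfg <- sim_config(seed = 77, grid = toy_grid(128))
  d1 <- simulate_dataset(cfg, 4)
  d2 <- simulate_dataset(cfg, 4)
  expect_identical(d1[[3]]$fid$samples, d2[[3]]$fid$samples)
  expect_identical(d1[[3]]$truth_amplitudes, d2[[3]]$truth_amplitudes)

  expect_length(simulate_dataset(cfg, 0), 0)

  # noiseless record is exactly metabolites + water
  cfg0 <- sim_config(seed = 5, noise = FALSE, grid = toy_grid(128))
  r <- simulate_dataset(cfg0, 1)[[1]]
  expect_equal(r$fid$samples, r$metab_fid$samples + r$water_truth$samples,
               tolerance = 1e-14)

  # noisy record: residual is the recorded noise realization
  rn <- simulate_dataset(sim_config(seed = 5, grid = toy_grid(128)), 1)[[1]]
  noise <- rn$fid$samples - rn$metab_fid$samples - rn$water_truth$samples
  expect_equal(stats::sd(c(Re(noise), Im(noise))), rn$noise_sd, tolerance = 0.25)
})

test_that("drawn parameters stay inside their stated supports", {
  cfg <- sim_config(seed = 9, grid = toy_grid(64))
  ds <- simulate_dataset(cfg, 200)
  for (r in ds) {
    p <- r$metab_params
    expect_true(all(p$shift_hz >= -20 & p$shift_hz <= 20))
    expect_true(all(p$damping_hz >= 1.5 & p$damping_hz <= 6))
    expect_true(all(abs(p$phase) <= pi / 4))
    expect_true(all(p$scale >= 0.1 & p$scale <= 2))
    expect_true(r$snr >= 5 && r$snr <= 50)
    wc <- r$water_components
    expect_true(all(wc$amplitude >= 10 * c(1, .33, .33, .11, .11) - 1e-12))
    expect_true(all(wc$amplitude <= 150 * c(1, .33, .33, .11, .11) + 1e-12))
    expect_true(all(wc$damping_hz >= 12 & wc$damping_hz <= 68))
  }
})

test_that("noise-free water truth is exactly a 5-pole HSVD model", {
  cfg <- sim_config(seed = 13, grid = std_grid())
  r <- simulate_dataset(cfg, 1)[[1]]
  comp <- hsvd_decompose(r$water_truth, hsvd_config(n_singular_values = 5))
  recon <- lorentzian_fid(comp, std_grid())
  rel <- sqrt(sum(Mod(recon$samples - r$water_truth$samples)^2) /
                sum(Mod(r$water_truth$samples)^2))
  expect_lt(rel, 1e-6)
})
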