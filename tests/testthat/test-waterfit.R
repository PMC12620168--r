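test_that("waterfit_loss equals a three-term brute-force computation", {
  g <- toy_grid(64)
  cfg <- waterfit_config(lambda_penalty = 1.3)
  comp <- lorentzian_components(c(5, 2, 1), c(30, 50, 10), c(4.7, 4.6, 4.9),
                                c(0.2, -1, 0.5))
  set.seed(21)
  target <- mrs_spectrum(complex(real = rnorm(64, sd = 5),
                                 imaginary = rnorm(64, sd = 5)), g)

  # independent oracle: naive DFT of a hand-rolled component sum, then
  # explicit loops over bins for each term
  t <- (0:63) / g$bandwidth_hz
  m <- complex(64)
  for (j in 1:3) {
    fhz <- (comp$freq_ppm[j] - g$carrier_ppm) * g$transmitter_mhz
    m <- m + comp$amplitude[j] * exp(-comp$damping_hz[j] * t) *
      exp(1i * (2 * pi * fhz * t + comp$phase[j]))
  }
  W <- naive_spectrum(m)
  ppm <- ppm_axis(g)
  mse <- 0; nb <- 0; pen <- 0; nm <- 0
  for (i in 1:64) {
    if (ppm[i] >= 4.4 && ppm[i] < 7.0) {
      mse <- mse + Re(W[i] - target$values[i])^2 + Im(W[i] - target$values[i])^2
      nb <- nb + 1
    }
    if (ppm[i] >= 0.4 && ppm[i] < 4.4) {
      pen <- pen + Mod(W[i])
      nm <- nm + 1
    }
  }
  expected <- mse / (2 * nb) + 1.3 * pen / nm + sum(comp$amplitude^2)
  got <- waterfit_loss(comp, target, cfg)
  expect_equal(as.numeric(got), expected, tolerance = 1e-10)

  # term decomposition is exposed
  terms <- attr(got, "terms")
  expect_equal(terms$mse + terms$band_penalty + terms$amp_penalty,
               as.numeric(got), tolerance = 1e-12)
})

test_that("degenerate loss cases behave as the formula dictates", {
  g <- toy_grid(64)
  cfg <- waterfit_config()
  set.seed(3)
  target <- mrs_spectrum(complex(real = rnorm(64), imaginary = rnorm(64)), g)
  # all-zero model: loss is just the water-band MSE against S
  zero <- lorentzian_components(0, 10, 4.7, 0)
  mw <- band_mask(g, 4.4, 7.0)
  expect_equal(as.numeric(waterfit_loss(zero, target, cfg)),
               sum(Mod(target$values[mw])^2) / (2 * sum(mw)), tolerance = 1e-12)

  # perfect fit with lambda = 0: MSE term exactly zero, penalties explicit
  comp <- lorentzian_components(4, 25, 4.75, 0.3)
  model <- water_model(comp, g)
  l <- waterfit_loss(comp, model, waterfit_config(lambda_penalty = 0))
  expect_equal(attr(l, "terms")$mse, 0, tolerance = 1e-18)
  expect_equal(attr(l, "terms")$band_penalty, 0)
  expect_equal(attr(l, "terms")$amp_penalty, 16)
})

test_that("analytic gradients match central finite differences", {
  g <- toy_grid(128)
  cfg <- waterfit_config()
  set.seed(2)
  S <- matrix(complex(real = rnorm(128), imaginary = rnorm(128)), 128, 1) * 10
  masks <- list(water = band_mask(g, 4.4, 7.0), metab = band_mask(g, 0.4, 4.4))
  masks$n_water <- sum(masks$water); masks$n_metab <- sum(masks$metab)
  A <- matrix(runif(7, -2, 5), 7, 1)
  w <- matrix(runif(7, 5, 50), 7, 1)
  f <- matrix(runif(7, -30, 30), 7, 1)       # offset Hz
  phi <- matrix(runif(7, -1, 1), 7, 1)
  gr <- watermrs:::.wf_loss_grad(A, w, f, phi, S, g, cfg, masks)
  lossfn <- function(A, w, f, phi)
    watermrs:::.wf_loss_grad(A, w, f, phi, S, g, cfg, masks)$loss
  eps <- 1e-6
  for (block in c("A", "w", "f", "phi")) {
    P <- switch(block, A = A, w = w, f = f, phi = phi)
    got <- switch(block, A = gr$gA, w = gr$gw, f = gr$gf, phi = gr$gphi)
    num <- vapply(1:7, function(j) {
      Pp <- P; Pp[j, 1] <- Pp[j, 1] + eps
      Pm <- P; Pm[j, 1] <- Pm[j, 1] - eps
      up <- switch(block, A = lossfn(Pp, w, f, phi), w = lossfn(A, Pp, f, phi),
                   f = lossfn(A, w, Pp, phi), phi = lossfn(A, w, f, Pp))
      dn <- switch(block, A = lossfn(Pm, w, f, phi), w = lossfn(A, Pm, f, phi),
                   f = lossfn(A, w, Pm, phi), phi = lossfn(A, w, f, Pm))
      (up - dn) / (2 * eps)
    }, 0)
    expect_lt(max(abs(num - got) / pmax(abs(got), 1e-6)), 1e-4)
  }
})

test_that("clamp_frequencies projects onto [4.4, 5.0] ppm", {
  cfg <- waterfit_config()
  comp <- lorentzian_components(c(1, 1, 1), 30, c(5.3, 4.7, 4.2), 0)
  out <- clamp_frequencies(comp, cfg)
  expect_equal(out$freq_ppm, c(5.0, 4.7, 4.4))
  expect_equal(out$amplitude, comp$amplitude)
  expect_equal(out$damping_hz, comp$damping_hz)
})

test_that("fit_water leaves water-free spectra essentially untouched", {
  # input with exactly zero water-band energy (metabolite peaks, with the
  # water band explicitly blanked so even their Lorentzian tails vanish)
  g <- std_grid()
  metab <- lorentzian_components(c(5, 3), c(4, 4), c(2.01, 3.03), 0)
  v <- to_spectrum(lorentzian_fid(metab, g))$values
  v[band_mask(g, 4.4, 7.0)] <- 0
  s <- mrs_spectrum(v, g)
  fit <- fit_water(s, waterfit_config(max_iterations = 200))
  # the amplitude penalty drives fitted amplitudes toward zero
  expect_lt(sum(fit$components$amplitude), 0.5)
  mm <- band_mask(g, 0.4, 4.4)
  expect_lt(max(Mod(fit$cleaned_spectrum$values[mm] - s$values[mm])) /
              max(Mod(s$values[mm])), 0.01)
})

test_that("fit_water removes a strong water peak over weak metabolites", {
  g <- std_grid()
  water <- lorentzian_components(100, 40, 4.7, 0.4)
  metab <- lorentzian_components(c(1.12, 1.33), c(4, 4), c(2.01, 3.03), 0)
  s <- to_spectrum(lorentzian_fid(rbind(water, metab), g))
  fit <- fit_water(s, waterfit_config())
  mw <- band_mask(g, 4.4, 7.0)
  e_in <- sum(Mod(s$values[mw])^2)
  e_out <- sum(Mod(fit$cleaned_spectrum$values[mw])^2)
  expect_lt(e_out / e_in, 0.05)

  # invariants: exact subtraction, clamped frequencies, loss decreased
  expect_equal(fit$cleaned_spectrum$values + fit$water_spectrum$values,
               s$values, tolerance = 1e-14)
  expect_true(all(fit$components$freq_ppm >= 4.4 & fit$components$freq_ppm <= 5.0))
  expect_lt(utils::tail(cummin(fit$loss_trace), 1), fit$loss_trace[1])
})

test_that("batch fitting equals per-spectrum fitting", {
  g <- std_grid()
  set.seed(31)
  mk <- function() {
    comp <- lorentzian_components(runif(1, 40, 120), runif(1, 20, 60),
                                  runif(1, 4.6, 4.8), runif(1, -pi, pi))
    to_spectrum(lorentzian_fid(comp, g))
  }
  s1 <- mk(); s2 <- mk()
  cfg <- waterfit_config(max_iterations = 120)
  batch <- fit_water(list(s1, s2, s1, s2, s1), cfg)
  solo <- fit_water(s1, cfg)
  # duplicates in a batch give identical results, equal to the solo fit
  expect_identical(batch[[1]]$components, batch[[3]]$components)
  expect_identical(batch[[2]]$components, batch[[4]]$components)
  expect_equal(batch[[1]]$components, solo$components, tolerance = 1e-12)
  expect_equal(batch[[1]]$loss_trace, solo$loss_trace, tolerance = 1e-12)
})

test_that("cleaning improves metabolite-band fidelity on simulated records", {
  # noise-free so the water tail is the only corruption of the metabolite band
  cfg <- sim_config(seed = 41, noise = FALSE,
                    water = water_sim_config(amp_factor_range = c(50, 150)))
  ds <- simulate_dataset(cfg, 3)
  g <- cfg$grid
  mm <- band_mask(g, 0.4, 4.4)
  fits <- fit_water(lapply(ds, function(r) to_spectrum(r$fid)))
  for (i in seq_along(ds)) {
    truth <- Re(to_spectrum(ds[[i]]$metab_fid)$values[mm])
    before <- cor(Re(to_spectrum(ds[[i]]$fid)$values[mm]), truth)
    after <- cor(Re(fits[[i]]$cleaned_spectrum$values[mm]), truth)
    expect_gt(after, before)
  }
})
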