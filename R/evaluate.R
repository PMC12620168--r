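#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of `fitted` against `truth`. Can be negative
#' for fits worse than the mean; errors on zero truth variance.
#'
#' @param truth,fitted Numeric vectors of equal length >= 2.
#' @return Scalar in `(-Inf, 1]`.
#' @export
r_squared <- function(truth, fitted) {
  stopifnot(length(truth) == length(fitted), length(truth) >= 2L)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("R^2 undefined: truth has zero variance", call. = FALSE)
  1 - sum((truth - fitted)^2) / ss_tot
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean of `a - b`) and 1.96-SD limits of agreement of two paired
#' measurement series, plus the per-pair differences and means for
#' plotting.
#'
#' @param a,b Numeric vectors of equal length >= 2 (convention: reference
#'   method minus evaluated method when comparing against a gold standard).
#' @return A list of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `differences`, `means`, `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 differences = d, means = (a + b) / 2, n = length(a)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.5g, LoA = [%.5g, %.5g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' @param x A [bland_altman()] object.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of methods",
                 ylab = "difference", ...)
  graphics::abline(h = x$bias)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

MAIN_METABOLITES <- c("Cho", "Cr", "NAA")

#' Run the simulated water-removal benchmark
#'
#' End-to-end paired benchmark: simulate `n` spectra, remove the water
#' residual with each requested method on the *same* records, quantify
#' metabolites with an identical fitting configuration, and aggregate
#' percentage errors, R-squared values and paired comparisons.
#'
#' Methods: `"waterfit"` (the seven-Lorentzian gradient fit), `"hsvd"`
#' (Hankel-SVD comparator), `"none"` (no removal) and `"oracle"`
#' (subtract the true simulated water signal — a lower bound on
#' removal-induced error).
#'
#' @param config A [sim_config()]; its `seed` (or the `seed` argument)
#'   makes the report reproducible.
#' @param n Number of simulated spectra.
#' @param methods Character vector of method names.
#' @param seed Optional seed overriding `config$seed`.
#' @param waterfit_cfg,hsvd_cfg,metab_cfg Stage configurations.
#' @param keep_amplitudes Keep per-spectrum fitted/truth amplitude tables in
#'   the report (default `TRUE`; needed for R-squared and Bland-Altman).
#' @return A `benchmark_report`: list with `error_table` (methods x
#'   metabolites mean percentage error + `Average` column),
#'   `main_summary` (per method, mean and SD of errors pooled over
#'   Cho/Cr/NAA), `r_squared` (methods x main metabolites), `errors`
#'   (per-method matrices n x metabolites), `amplitudes`, `truth`,
#'   `timings_sec`, `n_spectra`, `seed`, `methods`.
#' @export
run_benchmark <- function(config = sim_config(), n = 100L,
                          methods = c("waterfit", "hsvd"),
                          seed = NULL,
                          waterfit_cfg = waterfit_config(),
                          hsvd_cfg = hsvd_config(),
                          metab_cfg = metab_config(),
                          keep_amplitudes = TRUE) {
  stopifnot(n >= 1L, length(methods) >= 1L)
  methods <- match.arg(methods, c("waterfit", "hsvd", "none", "oracle"),
                       several.ok = TRUE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dataset <- simulate_dataset(config, n)
  grid <- config$grid
  basis <- metab_basis(config$metabolites, grid)
  truth <- do.call(rbind, lapply(dataset, `[[`, "truth_amplitudes"))

  cleaned_for <- function(method) {
    switch(method,
      none = lapply(dataset, function(r) to_spectrum(r$fid)),
      oracle = lapply(dataset, function(r)
        to_spectrum(fid_signal(r$fid$samples - r$water_truth$samples, grid))),
      waterfit = {
        fits <- fit_water(lapply(dataset, function(r) to_spectrum(r$fid)),
                          waterfit_cfg)
        lapply(fits, `[[`, "cleaned_spectrum")
      },
      hsvd = lapply(dataset, function(r)
        to_spectrum(remove_water_hsvd(r$fid, hsvd_cfg)$cleaned_fid)))
  }

  amplitudes <- list(); errors <- list(); timings <- c()
  for (m in methods) {
    t0 <- proc.time()[["elapsed"]]
    cleaned <- cleaned_for(m)
    t1 <- proc.time()[["elapsed"]]
    fits <- fit_metabolites(cleaned, basis, metab_cfg)
    t2 <- proc.time()[["elapsed"]]
    amp <- do.call(rbind, lapply(fits, function(f) f$params$amplitudes))
    amplitudes[[m]] <- amp
    errors[[m]] <- 100 * abs(truth - amp) / truth
    timings <- rbind(timings, c(removal = t1 - t0, fitting = t2 - t1))
  }
  rownames(timings) <- methods

  met_names <- basis$names
  error_table <- do.call(rbind, lapply(methods, function(m) {
    e <- colMeans(errors[[m]])
    c(e, Average = mean(e))
  }))
  rownames(error_table) <- methods

  main_summary <- do.call(rbind, lapply(methods, function(m) {
    pooled <- as.vector(errors[[m]][, MAIN_METABOLITES, drop = FALSE])
    c(mean = mean(pooled), sd = stats::sd(pooled))
  }))
  rownames(main_summary) <- methods

  r2 <- do.call(rbind, lapply(methods, function(m) {
    vapply(MAIN_METABOLITES, function(met)
      r_squared(truth[, met], amplitudes[[m]][, met]), 0)
  }))
  rownames(r2) <- methods

  structure(list(error_table = error_table, main_summary = main_summary,
                 r_squared = r2, errors = errors,
                 amplitudes = if (keep_amplitudes) amplitudes else NULL,
                 truth = if (keep_amplitudes) truth else NULL,
                 timings_sec = timings, n_spectra = n,
                 seed = config$seed, methods = methods),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d spectra, seed %d\n", x$n_spectra, x$seed))
  cat("\nMean percentage error per metabolite:\n")
  print(round(x$error_table, 2))
  cat("\nMain metabolites (Cho, Cr, NAA) pooled:\n")
  print(round(x$main_summary, 2))
  cat("\nR^2 (main metabolites):\n")
  print(round(x$r_squared, 4))
  invisible(x)
}

#' Paired comparison of two methods in a benchmark report
#'
#' Difference of the per-spectrum main-metabolite errors of two methods of
#' the same report (paired design), with a paired t-test.
#'
#' @param report A [run_benchmark()] report containing both methods.
#' @param a,b Method names.
#' @return List with `mean_diff` (mean error a minus mean error b, in
#'   percentage points, pooled over main metabolites), `t_test` (paired
#'   [stats::t.test()] on the per-spectrum pooled errors).
#' @export
paired_comparison <- function(report, a, b) {
  stopifnot(inherits(report, "benchmark_report"),
            a %in% report$methods, b %in% report$methods)
  ea <- rowMeans(report$errors[[a]][, MAIN_METABOLITES, drop = FALSE])
  eb <- rowMeans(report$errors[[b]][, MAIN_METABOLITES, drop = FALSE])
  list(mean_diff = mean(ea) - mean(eb),
       t_test = stats::t.test(ea, eb, paired = TRUE))
}

#' Write a benchmark report to disk
#'
#' Serializes the aggregate tables as `error_table.csv`,
#' `main_summary.csv`, `r_squared.csv` and `summary.json` under `dir`.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$error_table, file.path(dir, "error_table.csv"))
  utils::write.csv(report$main_summary, file.path(dir, "main_summary.csv"))
  utils::write.csv(report$r_squared, file.path(dir, "r_squared.csv"))
  jsonlite::write_json(
    list(n_spectra = report$n_spectra, seed = report$seed,
         methods = report$methods,
         main_summary = as.data.frame(report$main_summary),
         timings_sec = as.data.frame(report$timings_sec)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
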