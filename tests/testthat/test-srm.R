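test_that("pump-probe kinetics recover generating rates and background", {
  t <- seq(0, 3, by = 0.005)
  # single-exponential truth: average rate = the rate, background = offset
  # fraction of the initial fluorescence
  cyc1 <- lapply(1:25, function(i) 0.9 * exp(-2.5 * t) + 0.1)
  pp1 <- pump_probe_off_kinetics(cyc1, t = t)
  expect_equal(pp1$avg_rate, 2.5, tolerance = 0.01)
  expect_equal(pp1$background_level, 0.1, tolerance = 0.01)
  # biexponential truth: amplitude-weighted mean rate
  truth <- function(tt) 0.6 * exp(-4 * tt) + 0.3 * exp(-0.8 * tt) + 0.1
  set.seed(2)
  cyc2 <- lapply(1:25, function(i) truth(t) + rnorm(length(t), 0, 0.002))
  pp2 <- pump_probe_off_kinetics(cyc2, t = t)
  expect_equal(pp2$avg_rate, (0.6 * 4 + 0.3 * 0.8) / 0.9, tolerance = 0.02)
  # degenerate inputs
  expect_error(pump_probe_off_kinetics(lapply(1:5, function(i) rep(1, 10))),
               "zero-amplitude")
  expect_error(pump_probe_off_kinetics(lapply(1:5, function(i) seq(0, 1,
                                                                   length.out = 50))),
               "does not decay")
})

test_that("rate estimates are invariant to uniform amplitude scaling", {
  t <- seq(0, 3, by = 0.01)
  cyc <- lapply(1:10, function(i) 0.7 * exp(-3 * t) + 0.2 * exp(-0.5 * t) + 0.05)
  a <- pump_probe_off_kinetics(cyc, t = t)
  b <- pump_probe_off_kinetics(lapply(cyc, `*`, 5), t = t)
  expect_equal(b$avg_rate, a$avg_rate, tolerance = 1e-6)
  expect_equal(b$background_level, a$background_level, tolerance = 1e-6)
})

test_that("ON-series normalisation fixes the equilibrium level at 1", {
  sch <- illumination_schedule(list(
    list(wavelength = 488, intensity = 0.2, n_pulses = 30, pulse_rate = 10),
    list(wavelength = 405, intensity = 0.1, n_pulses = 30, pulse_rate = 10)))
  s <- sensor_model(kd = 0.46)
  trs <- replicate(3, simulate_trace(s, sch, ca = 100), simplify = FALSE)
  out <- normalize_on_series(trs)
  eq <- out[[1]]$s[out[[1]]$phase_id == out[[1]]$phase_id[1]]
  expect_equal(mean(eq), 1, tolerance = 1e-12)
  # scale invariance
  scaled <- lapply(trs, function(tr)
    switching_trace(tr$t, tr$s * 5, tr$phase_id, schedule = attr(tr, "schedule")))
  out5 <- normalize_on_series(scaled)
  expect_equal(out5[[1]]$s, out[[1]]$s, tolerance = 1e-12)
  zero <- list(switching_trace(1:10, rep(0, 10), rep(1L, 10)))
  expect_error(normalize_on_series(zero), "zero")
})

test_that("ON-switching plateau increases with 405-nm power", {
  s <- sensor_model(kd = 0.46, sigma_on = 2)
  plateau <- vapply(c(0.03, 0.1, 0.2, 0.37), function(p) {
    sch <- illumination_schedule(list(
      list(wavelength = 488, intensity = 0.21, n_pulses = 40,
           pulse_rate = 10),
      list(wavelength = 405, intensity = p, n_pulses = 10, pulse_rate = 10)))
    tr <- simulate_trace(s, sch, ca = 100)
    tail(tr$s, 1)
  }, numeric(1))
  expect_true(all(diff(plateau) > 0))
})

test_that("double-Gaussian FWHM matches the closed form", {
  x <- seq(-400, 400, by = 4)
  f1 <- double_gaussian_fwhm(list(x = x, y = exp(-x^2 / (2 * 50^2))))
  expect_length(f1, 1)
  expect_equal(f1[1], 2 * sqrt(2 * log(2)) * 50, tolerance = 1e-3)
  # two peaks 80 nm apart, sigma 25 nm
  y2 <- exp(-(x + 40)^2 / (2 * 25^2)) + 0.9 * exp(-(x - 40)^2 / (2 * 25^2))
  f2 <- double_gaussian_fwhm(list(x = x, y = y2))
  expect_length(f2, 2)
  expect_equal(as.numeric(f2), rep(2 * sqrt(2 * log(2)) * 25, 2),
               tolerance = 0.02)
  expect_error(double_gaussian_fwhm(list(x = x, y = rep(1, length(x)))),
               "no peak")
  # amplitude scaling leaves widths unchanged
  f3 <- double_gaussian_fwhm(list(x = x, y = 7 * y2))
  expect_equal(as.numeric(f3), as.numeric(f2), tolerance = 1e-6)
})

test_that("dual-Gaussian PSF kernel is normalised, centred and mixture-widened", {
  psf <- dual_gaussian_psf(pixel_size = 10)
  k <- psf$values
  expect_equal(sum(k), 1, tolerance = 1e-9)
  expect_identical(nrow(k), ncol(k))
  expect_identical(nrow(k) %% 2L, 1L)
  ctr <- (nrow(k) + 1L) %/% 2L
  expect_identical(which.max(k), (ctr - 1L) * nrow(k) + ctr)
  expect_equal(k, t(k), tolerance = 1e-12)          # symmetric
  # measured FWHM of the mixture: >= narrow width, < 60 nm
  prof <- k[ctr, ]
  xs <- (seq_along(prof) - ctr) * psf$pixel_size
  half <- max(prof) / 2
  i1 <- max(which(prof < half & xs < 0)); i2 <- min(which(prof < half & xs > 0))
  fw <- approx(prof[c(i2 - 1, i2)], xs[c(i2 - 1, i2)], xout = half)$y -
    approx(prof[c(i1, i1 + 1)], xs[c(i1, i1 + 1)], xout = half)$y
  expect_gte(fw, 50)
  expect_lt(fw, 60)
  # wide_amp_frac = 0: pure Gaussian, central value matches closed form
  p0 <- dual_gaussian_psf(wide_amp_frac = 0, pixel_size = 5)
  k0 <- p0$values
  sn <- 50 / (2 * sqrt(2 * log(2)))
  ref <- exp(-(((seq_len(nrow(k0)) - (nrow(k0) + 1) / 2) * 5)^2) / (2 * sn^2))
  ref2 <- outer(ref, ref)
  expect_equal(k0, ref2 / sum(ref2), tolerance = 1e-6)
  expect_error(dual_gaussian_psf(pixel_size = 30), "coarse")
  # area mode carries the stated energy fraction in the wide component
  pa <- dual_gaussian_psf(pixel_size = 5, amp_mode = "area")
  expect_equal(sum(pa$values), 1, tolerance = 1e-9)
})

test_that("Richardson-Lucy deconvolution conserves flux and sharpens", {
  psf <- dual_gaussian_psf(pixel_size = 10)
  img <- matrix(0, 64, 64)
  img[30, 30] <- 1; img[30, 38] <- 1
  blurred <- pmax(caswitch:::conv2_reflect(img, psf$values), 0)
  dec <- rl_deconvolve(blurred, psf, 5)
  expect_true(all(dec >= 0))
  expect_lt(abs(sum(dec) - sum(blurred)) / sum(blurred), 1e-6)
  # identity under a delta kernel
  expect_equal(rl_deconvolve(blurred, psf_kernel(matrix(1, 1, 1)), 5),
               blurred, tolerance = 1e-12)
  # zero iterations return the input unchanged
  expect_identical(rl_deconvolve(blurred, psf, 0), blurred)
  # contrast between two points strictly increases
  contrast <- function(m) (max(m[30, c(30, 38)]) - m[30, 34]) /
    max(m[30, c(30, 38)])
  expect_gt(contrast(dec), contrast(blurred))
  expect_error(rl_deconvolve(matrix(c(-1, 0, 0, 0), 2, 2), psf), "non-negative")
})
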