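test_that("hill_fraction follows the single-site isotherm", {
  expect_equal(hill_fraction(500, 72, 1), 500 / 572, tolerance = 1e-12)
  expect_equal(round(hill_fraction(500, 72, 1), 3), 0.874)
  for (n in c(0.5, 1, 2.3)) expect_equal(hill_fraction(72, 72, n), 0.5)
  expect_identical(hill_fraction(0, 72, 1), 0)
  # monotone on a log grid, 0.5 at kd, -> 1 at saturation
  ca <- 10^seq(-3, 5, length.out = 40)
  f <- hill_fraction(ca, 72, 1.7)
  expect_true(all(diff(f) > 0))
  expect_gt(hill_fraction(1e8, 72, 1), 0.999)
  expect_error(hill_fraction(-1, 72, 1), "ca")
  expect_error(hill_fraction(10, -1, 1), "kd")
  expect_error(hill_fraction(10, 72, 0), "n")
})

test_that("simulate_trace matches the closed-form single-species decay", {
  sch <- spectrometer_schedule(n_pulses = 80L)
  s <- single_species_sensor(rate = 2.5)
  tr <- simulate_trace(s, sch, ca = 1e6)
  f <- hill_fraction(1e6, s$kd, s$hill_n)
  expect_equal(tr$s, f * exp(-2.5 * tr$t), tolerance = 1e-12)
})

test_that("the Ca2+-free state gives a flat, non-switching trace", {
  s <- sensor_model(eps_free = 0.1, brightness = 2, dark_offset = 0.05)
  tr <- simulate_trace(s, oa_tomography_schedule(n_cycles = 2L), ca = 0)
  expect_true(all(abs(tr$s - (0.1 * 2 + 0.05)) < 1e-14))
})

test_that("simulate_trace is seed-reproducible and seed-free when noiseless", {
  sch <- small_tomo_schedule()
  s <- cyto_sensor()
  a <- simulate_trace(s, sch, 5, noise_sd = 0.01, seed = 11)
  b <- simulate_trace(s, sch, 5, noise_sd = 0.01, seed = 11)
  expect_identical(a$s, b$s)
  c <- simulate_trace(s, sch, 5, noise_sd = 0.01, seed = 12)
  expect_false(identical(a$s, c$s))
  set.seed(99)
  d <- simulate_trace(s, sch, 5, noise_sd = 0)
  set.seed(1234)
  e <- simulate_trace(s, sch, 5, noise_sd = 0)
  expect_identical(d$s, e$s)
})

test_that("effective tau is strictly decreasing in Ca2+ for two-species sensors", {
  s <- cyto_sensor()
  sch <- spectrometer_schedule()
  grid <- c(0.1, 0.46, 1, 4.6, 10, 46) # 6 concentrations around kd
  taus <- vapply(grid, function(ca)
    effective_tau(simulate_trace(s, sch, ca))$tau, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("effective_tau recovers known decays and flags degenerate traces", {
  t <- seq(0, 12, by = 0.1)
  s <- 1 * exp(-t / 2) + 0.1
  fit <- effective_tau(switching_trace(t, s))
  expect_true(fit$valid)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$y0, 0.1, tolerance = 1e-6)
  # fixed offset
  fit2 <- effective_tau(switching_trace(t, s), y0_fixed = 0.1)
  expect_true(fit2$y0_fixed)
  expect_equal(fit2$tau, 2, tolerance = 1e-8)
  # constant trace: invalid, no exception
  flat <- effective_tau(switching_trace(t, rep(1, length(t))))
  expect_false(flat$valid)
  expect_true(is.na(flat$tau))
  expect_error(effective_tau(switching_trace(0:2, c(1, 0.5, 0.2))),
               "at least 4")
})

test_that("effective_tau agrees with a dense grid-search oracle on biexponential traces", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- seq(0, 10, by = 0.05)
    a <- runif(1, 0.3, 0.7)
    y0 <- runif(1, 0, 0.2)
    s <- a * exp(-3 * t) + (1 - a) * exp(-0.4 * t) + y0
    fit <- effective_tau(switching_trace(t, s), y0_fixed = y0)
    oracle <- grid_search_tau(t, s, y0)
    expect_equal(fit$tau, oracle, tolerance = 1e-3)
  }
})

test_that("global biexponential fit recovers shared rates across traces", {
  t <- seq(0, 8, by = 0.05)
  mk <- function(a) switching_trace(t, a * exp(-3 * t) +
                                      (1 - a) * exp(-0.4 * t) + 0.05)
  traces <- lapply(c(0.15, 0.4, 0.7, 0.9), mk)
  fit <- global_biexp(traces)
  expect_equal(fit$k_fast, 3, tolerance = 0.02)
  expect_equal(fit$k_slow, 0.4, tolerance = 0.02)
  expect_lte(fit$residual, fit$residual_single + 1e-12)
})

test_that("single-species traces collapse the biexponential to one amplitude", {
  t <- seq(0, 8, by = 0.05)
  traces <- lapply(c(0.5, 1, 2), function(A)
    switching_trace(t, A * exp(-1.2 * t) + 0.02))
  fit <- global_biexp(traces)
  expect_lte(fit$residual, fit$residual_single + 1e-8)
  # one component carries ~no amplitude in every trace
  small <- pmin(abs(fit$amps[, "A_fast"]), abs(fit$amps[, "A_slow"]))
  expect_true(all(small < 1e-4 * c(0.5, 1, 2)))
})

test_that("global biexponential rates survive noise (Monte Carlo)", {
  t <- seq(0, 8, by = 0.05)
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    traces <- lapply(c(0.2, 0.5, 0.8), function(a) {
      s25 <- rowMeans(vapply(1:25, function(i)
        a * exp(-3 * t) + (1 - a) * exp(-0.4 * t) + 0.05 +
          rnorm(length(t), 0, 0.01), numeric(length(t))))
      switching_trace(t, s25)
    })
    fit <- global_biexp(traces)
    if (abs(fit$k_fast - 3) / 3 < 0.1 && abs(fit$k_slow - 0.4) / 0.4 < 0.1)
      ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("global_biexp rejects misaligned time bases", {
  t <- seq(0, 5, by = 0.1)
  a <- switching_trace(t, exp(-t))
  b <- switching_trace(t * 1.1, exp(-t))
  expect_error(global_biexp(list(a, b)), "aligned")
})

test_that("photo-fatigue is recovered from per-cycle amplitudes", {
  sch <- oa_tomography_schedule(n_cycles = 10L, n_pulses = 60L,
                                pulses_per_frame = 1L)
  s0 <- cyto_sensor(fatigue_per_cycle = 0)
  expect_lt(measure_fatigue(simulate_trace(s0, sch, 39)), 1e-6)
  s5 <- cyto_sensor(fatigue_per_cycle = 0.05)
  expect_equal(measure_fatigue(simulate_trace(s5, sch, 39)), 0.05,
               tolerance = 0.02)
  # noisy Monte-Carlo: mean over 20 seeds within 0.005 of truth
  s2 <- cyto_sensor(fatigue_per_cycle = 0.02)
  est <- vapply(1:20, function(seed)
    measure_fatigue(simulate_trace(s2, sch, 39, noise_sd = 0.01,
                                   seed = seed)), numeric(1))
  expect_lt(abs(mean(est) - 0.02), 0.005)
  short <- simulate_trace(s5, oa_tomography_schedule(n_cycles = 2L), 39)
  expect_error(measure_fatigue(short), "3 full cycles")
})

test_that("sensor and schedule constructors validate their invariants", {
  expect_error(sensor_model(kd = -1), "kd")
  expect_error(sensor_model(sigma_fast = 0.1, sigma_slow = 0.5),
               "sigma_fast >= sigma_slow")
  expect_error(sensor_model(fatigue_per_cycle = 1), "fatigue")
  expect_error(illumination_schedule(list()), "at least one phase")
  expect_error(oa_tomography_schedule(n_pulses = 100L, pulses_per_frame = 3L),
               "divide")
  expect_identical(n_frames(oa_tomography_schedule()), 800L)
})
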