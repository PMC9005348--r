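test_that("fourier switching score separates modulated from flat traces", {
  s <- cyto_sensor()
  sch <- oa_tomography_schedule(n_cycles = 10L, n_pulses = 60L,
                                pulses_per_frame = 5L)
  tr <- simulate_trace(s, sch, 39)
  # a pure 10-cycle square switching wave concentrates > half its spectral
  # magnitude at the cycle frequency (odd harmonics 1, 1/3, ..., 1/9)
  sq_sched <- oa_tomography_schedule(n_cycles = 10L, n_pulses = 10L,
                                     pulses_per_frame = 1L)
  sq <- switching_trace(tr$t[1:200], rep(rep(c(1, 0), each = 10), 10),
                        rep(1L, 200), schedule = sq_sched)
  expect_gt(fourier_switch_score(sq), 0.5)
  # the exponential switching wave of a saturated sensor scores far above
  # both the mask threshold and the white-noise expectation
  expect_gt(fourier_switch_score(tr), 0.4)
  flat <- switching_trace(tr$t, rep(2, nrow(tr)), tr$phase_id,
                          schedule = sch)
  expect_identical(fourier_switch_score(flat), 0)
  # invariant to adding a constant
  shifted <- switching_trace(tr$t, tr$s + 3.7, tr$phase_id, schedule = sch)
  expect_equal(fourier_switch_score(shifted), fourier_switch_score(tr),
               tolerance = 1e-10)
  one_cycle <- oa_tomography_schedule(n_cycles = 1L)
  tr1 <- simulate_trace(s, one_cycle, 39)
  expect_error(fourier_switch_score(tr1), "2 full cycles")
})

test_that("white-noise traces score at the flat-spectrum expectation", {
  n_frames <- 200L
  n_cycles <- 10L
  n_bins <- n_frames %/% 2          # positive non-zero frequencies
  scores <- vapply(1:100, function(seed) {
    set.seed(seed)
    caswitch:::fourier_scores_matrix(matrix(rnorm(n_frames), ncol = 1),
                                     n_cycles)
  }, numeric(1))
  expect_lt(abs(mean(scores) - 1 / n_bins), 3 * sd(scores) / sqrt(100))
})

test_that("noiseless phantom classification equals the ground-truth sensor mask", {
  s <- cyto_sensor()
  sch <- small_tomo_schedule()
  lay <- small_phantom_layout()
  stk <- make_phantom_stack(lay, s, sch)
  maps <- classify_pixels(stk)
  truth <- layout_truth_masks(lay)
  expect_identical(maps$mask, truth$sensor)
  expect_identical(sum(maps$mask & truth$blood), 0L)
  # threshold-free limit: mask = all pixels with valid fits
  maps0 <- classify_pixels(stk, theta_f = 0, theta_r = 0)
  expect_identical(maps0$mask, !is.na(maps0$r2))
})

test_that("classification reaches F1 >= 0.95 at in-disk SNR 10", {
  s <- cyto_sensor()
  sch <- small_tomo_schedule()
  lay <- small_phantom_layout()
  truth <- layout_truth_masks(lay)
  # switching amplitude of the weakest sensor tube sets the SNR
  amp <- vapply(c(1.35, 39), function(ca)
    diff(range(simulate_trace(cyto_sensor(), sch, ca)$s)), numeric(1))
  noise_sd <- min(amp) / 10
  f1 <- vapply(1:10, function(seed) {
    stk <- make_phantom_stack(lay, s, sch, noise_sd = noise_sd, seed = seed)
    m <- classify_pixels(stk)$mask
    tp <- sum(m & truth$sensor)
    2 * tp / (2 * tp + sum(m & !truth$sensor) + sum(!m & truth$sensor))
  }, numeric(1))
  expect_gte(mean(f1), 0.95)
})

test_that("reference offset recovers the generator's non-switching level", {
  s <- cyto_sensor(eps_free = 0.1, dark_offset = 0.02)
  sch <- small_tomo_schedule()
  lay <- small_phantom_layout(ca = c(1.35, 1e7))   # fully saturated reference
  stk <- make_phantom_stack(lay, s, sch)
  y0 <- reference_offset(stk, list(x = 34, y = 16, r = 5))
  f <- hill_fraction(1e7, s$kd, s$hill_n)
  truth <- s$eps_free * (1 - f) * s$brightness + s$dark_offset
  expect_lt(abs(y0 - truth), 1e-6)
  expect_error(reference_offset(stk, list(x = 4, y = 44, r = 3)),
               "not a usable decay")
  # noisy ROI average still lands within 2%
  stk2 <- make_phantom_stack(lay, s, sch, noise_sd = 0.02, seed = 3)
  y0n <- reference_offset(stk2, list(x = 34, y = 16, r = 5))
  expect_equal(y0n, truth, tolerance = 0.02)
})

test_that("pixel kinetics maps are exact for uniform fluence and NaN off-mask", {
  s <- cyto_sensor()
  sch <- small_tomo_schedule()
  lay <- small_phantom_layout()
  stk <- make_phantom_stack(lay, s, sch)
  maps <- classify_pixels(stk)
  y0 <- reference_offset(stk, list(x = 34, y = 16, r = 5))
  tmap <- fit_pixel_kinetics(stk, maps$mask, y0)
  truth <- layout_truth_masks(lay)
  for (i in 1:2) {
    tt <- tmap$tau[truth$region_id == i]
    expect_lt(sd(tt) / mean(tt), 1e-3)
  }
  # ordering: higher ca -> faster decay
  expect_lt(mean(tmap$tau[truth$region_id == 2]),
            mean(tmap$tau[truth$region_id == 1]))
  expect_true(all(is.na(tmap$tau[!maps$mask])))
  empty <- fit_pixel_kinetics(stk, matrix(FALSE, 48, 48), y0)
  expect_true(all(is.na(empty$tau)))
})

test_that("single-species saturating pixels give tau = 1/(sigma I) exactly", {
  rate <- 2
  s <- single_species_sensor(rate = rate)
  sch <- small_tomo_schedule()
  lay <- phantom_layout(32, 32, 0.1, regions = list(
    list(center = c(16, 16), radius = 5, kind = "sensor", ca = 1e6,
         strength = 1)), mu_eff = 0)
  stk <- make_phantom_stack(lay, s, sch)
  fit <- effective_tau(off_cycle_average(stk, x = 16, y = 16), y0_fixed = 0)
  expect_equal(fit$tau, 1 / rate, tolerance = 5e-3)
})

test_that("tau maps are invariant to global rescaling of the stack", {
  s <- cyto_sensor()
  sch <- small_tomo_schedule()
  lay <- small_phantom_layout()
  stk <- make_phantom_stack(lay, s, sch)
  stk2 <- stk
  stk2$frames <- stk$frames * 3.7
  m1 <- classify_pixels(stk)
  m2 <- classify_pixels(stk2)
  expect_identical(m1$mask, m2$mask)
  expect_equal(m2$fourier_score, m1$fourier_score, tolerance = 1e-9)
  t1 <- fit_pixel_kinetics(stk, m1$mask, 0.01)
  t2 <- fit_pixel_kinetics(stk2, m2$mask, 0.01 * 3.7)
  expect_equal(t2$tau, t1$tau, tolerance = 1e-6)
  expect_equal(t2$amplitude, t1$amplitude * 3.7, tolerance = 1e-6)
})

test_that("proportional ON-OFF difference isolates switchable regions", {
  on <- matrix(c(2, 4, 0, 1), 2, 2)
  off <- matrix(c(1, 4, 0, 0), 2, 2)
  d <- on_off_difference(on, off)
  expect_equal(d, matrix(c(0.5, 0, 0, 1), 2, 2))
  expect_equal(on_off_difference(on, on), matrix(0, 2, 2))
  expect_error(on_off_difference(on, matrix(0, 3, 3)), "same shape")
  # phantom: first vs last OFF-phase frame differs only inside sensor tubes
  s <- cyto_sensor()
  sch <- small_tomo_schedule()
  lay <- small_phantom_layout()
  stk <- make_phantom_stack(lay, s, sch)
  ft <- caswitch:::frame_table(sch)
  off_frames <- which(ft$wavelength == 488 & ft$cycle == 1)
  d2 <- on_off_difference(stk$frames[off_frames[1], , ],
                          stk$frames[tail(off_frames, 1), , ])
  truth <- layout_truth_masks(lay)
  expect_true(all(d2[truth$blood] == 0))
  expect_true(all(d2[truth$sensor] > 0))
  expect_true(all(d2[truth$region_id == 0] == 0))
})
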