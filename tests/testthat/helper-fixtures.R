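# Shared fixtures: small, fast variants of the study conditions.

# ER-affinity variant (binding/occupancy analyses)
er_sensor <- function(...) sensor_model(kd = 72, ...)

# Cytosolic-affinity variant used in the spectrometer/tomography analyses
cyto_sensor <- function(...) sensor_model(kd = 0.46, ...)

# Single-species sensor: both switchable species share one rate, no dim
# free-state background, no fatigue -> closed-form exponential traces.
single_species_sensor <- function(rate = 3, ...) {
  sensor_model(sigma_fast = rate, sigma_slow = rate, eps_free = 0,
               fatigue_per_cycle = 0, dark_offset = 0, ...)
}

# Reduced tomography schedule: full pulse structure, fewer frames.
small_tomo_schedule <- function(n_cycles = 4L, n_pulses = 60L,
                                pulses_per_frame = 5L) {
  oa_tomography_schedule(n_cycles = n_cycles, n_pulses = n_pulses,
                         pulses_per_frame = pulses_per_frame)
}

# Two-tube + one-blood phantom on a small grid.
small_phantom_layout <- function(ca = c(1.35, 39), mu_eff = 0) {
  phantom_layout(
    height = 48L, width = 48L, pixel_size = 0.1,
    regions = list(
      list(center = c(12, 16), radius = 5, kind = "sensor", ca = ca[1],
           strength = 1),
      list(center = c(34, 16), radius = 5, kind = "sensor", ca = ca[2],
           strength = 1),
      list(center = c(24, 36), radius = 5, kind = "blood", strength = 1.5)),
    mu_eff = mu_eff, illum_side = "top")
}

# Independent dense grid-search oracle for the fixed-offset exponential
# fit: profile the amplitude analytically on a tau grid, refine twice.
grid_search_tau <- function(t, s, y0) {
  t0 <- t - t[1]
  z <- s - y0
  ss_of <- function(tau) {
    b <- exp(-t0 / tau)
    a <- sum(b * z) / sum(b * b)
    sum((z - a * b)^2)
  }
  taus <- exp(seq(log(max(t0[2], 1e-4) / 10), log(max(t0) * 10),
                  length.out = 1000))
  best <- taus[which.min(vapply(taus, ss_of, numeric(1)))]
  for (i in 1:3) {
    taus <- seq(best * 0.9, best * 1.1, length.out = 1000)
    best <- taus[which.min(vapply(taus, ss_of, numeric(1)))]
  }
  best
}
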