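#' Simulate a photo-switching trace for one sensor and illumination schedule
#'
#' Forward model of Ca2+-dependent photo-switching.  A fraction
#' `f = hill_fraction(ca, kd, hill_n)` of molecules is Ca2+-bound and
#' switchable; the rest is dim (`eps_free`) and does not switch.  The
#' switchable pool is a two-species mixture: a fraction `alpha = f` switches
#' off with rate `sigma_fast * I` under 488-nm light and the remainder with
#' `sigma_slow * I`; 420/405-nm light switches both species back on with
#' rate `sigma_on * I`.  Rates scale linearly with intensity.  At every
#' ON-to-OFF (420/405 -> 488) phase boundary the switchable amplitude loses
#' an irreversible fraction `fatigue_per_cycle`.  The recorded signal is
#'
#'   s(t) = g(t) * brightness * f * (alpha * p_fast + (1 - alpha) * p_slow)
#'        + eps_free * (1 - f) * brightness + dark_offset
#'
#' with `p_fast`, `p_slow` the ON-state occupancies of the two species and
#' `g` the accumulated fatigue factor.  One sample is recorded per frame
#' (pulse samples averaged over `pulses_per_frame`), and optional additive
#' Gaussian noise is applied per frame.
#'
#' @param sensor A [sensor_model()].
#' @param schedule An [illumination_schedule()].
#' @param ca Free Ca2+ concentration, uM.
#' @param noise_sd Additive Gaussian noise standard deviation per frame,
#'   a.u.  With `noise_sd = 0` the trace is deterministic and independent of
#'   `seed`.
#' @param seed Integer seed for the noise; identical inputs and seed give a
#'   bit-identical trace.
#' @param intensity_scale Scalar multiplying every phase intensity (models
#'   local fluence); affects switching rates only, not amplitudes.
#' @return A [switching_trace()] with one sample per frame and the schedule
#'   and `ca` attached.
#' @examples
#' tr <- simulate_trace(sensor_model(), spectrometer_schedule(), ca = 39)
#' head(tr)
#' @export
simulate_trace <- function(sensor, schedule, ca, noise_sd = 0, seed = NULL,
                           intensity_scale = 1) {
  stopifnot(inherits(sensor, "sensor_model"),
            inherits(schedule, "illumination_schedule"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (intensity_scale <= 0) stop("`intensity_scale` must be > 0")
  pt <- pulse_table(schedule)
  f <- hill_fraction(ca, sensor$kd, sensor$hill_n)
  alpha <- f
  p_fast <- 1; p_slow <- 1; g <- 1
  prev_w <- NA_integer_
  s <- numeric(nrow(pt))
  for (pid in unique(pt$phase_id)) {
    idx <- which(pt$phase_id == pid)
    w <- pt$wavelength[idx[1]]
    intensity <- pt$intensity[idx[1]] * intensity_scale
    tin <- pt$t_in_phase[idx]
    # full phase duration n_pulses / pulse_rate (state carries to next phase)
    ph <- schedule$phases[[pt$phase_index[idx[1]]]]
    dur <- length(idx) / ph$pulse_rate
    if (w == 488) {
      if (!is.na(prev_w) && prev_w %in% c(420, 405))
        g <- g * (1 - sensor$fatigue_per_cycle)
      pf <- p_fast * exp(-sensor$sigma_fast * intensity * tin)
      ps <- p_slow * exp(-sensor$sigma_slow * intensity * tin)
      p_fast <- p_fast * exp(-sensor$sigma_fast * intensity * dur)
      p_slow <- p_slow * exp(-sensor$sigma_slow * intensity * dur)
    } else {
      pf <- 1 - (1 - p_fast) * exp(-sensor$sigma_on * intensity * tin)
      ps <- 1 - (1 - p_slow) * exp(-sensor$sigma_on * intensity * tin)
      p_fast <- 1 - (1 - p_fast) * exp(-sensor$sigma_on * intensity * dur)
      p_slow <- 1 - (1 - p_slow) * exp(-sensor$sigma_on * intensity * dur)
    }
    s[idx] <- g * sensor$brightness * f * (alpha * pf + (1 - alpha) * ps) +
      sensor$eps_free * (1 - f) * sensor$brightness + sensor$dark_offset
    prev_w <- w
  }
  # pulse samples -> frames
  ppf <- schedule$pulses_per_frame
  if (ppf > 1L) s <- colMeans(matrix(s, nrow = ppf))
  ft <- frame_table(schedule)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(length(s), 0, noise_sd)
             else withr::with_seed(seed, rnorm(length(s), 0, noise_sd))
    s <- s + noise
  }
  switching_trace(ft$t, s, ft$phase_id, schedule = schedule,
                  meta = list(ca = ca, intensity_scale = intensity_scale,
                              noise_sd = noise_sd, seed = seed))
}

#' Fit a single-exponential decay to an OFF-switching trace
#'
#' Least-squares fit of `A * exp(-t / tau) + y0` to a trace restricted to
#' one 488-nm OFF-switching phase (or a cycle-average of aligned phases).
#' The offset `y0` is free by default, or pinned with `y0_fixed` — the
#' tomography analysis fixes it from the highest-Ca2+ reference sample.
#' Degenerate inputs (constant trace, amplitude below the floor, fit
#' failure) return `valid = FALSE` rather than raising.
#'
#' @param trace A [switching_trace()] (or anything with `t` and `s`).
#' @param y0_fixed Optional fixed offset, a.u.
#' @param amplitude_floor Minimum |amplitude| for a valid fit; default 3x
#'   the trace noise estimate (median absolute deviation of first
#'   differences, scaled).
#' @return A `decay_fit`: list with `tau` (s), `amplitude`, `y0`,
#'   `y0_fixed` (flag), `r2`, `valid`.
#' @examples
#' tr <- simulate_trace(sensor_model(sigma_slow = 3), spectrometer_schedule(),
#'                      ca = 1e4)
#' effective_tau(tr)$tau  # ~1/3 s: single-species saturating limit
#' @export
effective_tau <- function(trace, y0_fixed = NULL, amplitude_floor = NULL) {
  t <- trace$t; s <- trace$s
  if (length(t) < 4L) stop("need at least 4 samples to fit a decay")
  fit_exp_decay(t, s, y0_fixed = y0_fixed, amplitude_floor = amplitude_floor)
}

# Core exponential fit, shared by effective_tau and the per-pixel mapper.
fit_exp_decay <- function(t, s, y0_fixed = NULL, amplitude_floor = NULL) {
  t0 <- t - t[1]
  fixed <- !is.null(y0_fixed)
  invalid <- structure(list(tau = NA_real_, amplitude = NA_real_,
                            y0 = if (fixed) y0_fixed else NA_real_,
                            y0_fixed = fixed, r2 = NA_real_, valid = FALSE),
                       class = "decay_fit")
  spread <- diff(range(s))
  noise_est <- mad(diff(s)) / sqrt(2)
  floor_ <- if (is.null(amplitude_floor)) 3 * noise_est else amplitude_floor
  if (!is.finite(spread) || spread <= max(1e-14 * max(abs(s), 1), 0))
    return(invalid)
  n <- length(s)
  y0_init <- if (fixed) y0_fixed else mean(tail(s, max(3L, n %/% 10L)))
  a_init <- s[1] - y0_init
  if (abs(a_init) < 1e-3 * spread) a_init <- spread
  tau_init <- {
    z <- (s - y0_init) / a_init
    ok <- which(z > 0.05)
    ti <- NA_real_
    if (length(ok) >= 3L) {
      sl <- unname(coef(lm(log(z[ok]) ~ t0[ok]))[2])
      if (is.finite(sl) && sl < 0) ti <- -1 / sl
    }
    if (!is.finite(ti) || ti <= 0) ti <- max(t0[n], 1e-6) / 3
    ti
  }
  df <- data.frame(t0 = t0, s = s)
  span <- max(t0[n], 1e-9)
  dt <- t0[2] - t0[1]
  tau_starts <- unique(pmax(c(tau_init, 2 * dt, span / 10, span / 2), 1e-9))
  fit <- NULL
  best_ss <- Inf
  for (ts in tau_starts) {
    cand <- tryCatch({
      if (fixed)
        minpack.lm::nlsLM(s ~ A * exp(-t0 / tau) + y0_fixed,
                          data = df, start = list(A = a_init, tau = ts),
                          lower = c(-Inf, 1e-12),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-12))
      else
        minpack.lm::nlsLM(s ~ A * exp(-t0 / tau) + y0,
                          data = df,
                          start = list(A = a_init, tau = ts, y0 = y0_init),
                          lower = c(-Inf, 1e-12, -Inf),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 500, ftol = 1e-12))
    }, error = function(e) NULL)
    if (!is.null(cand)) {
      ss <- sum(residuals(cand)^2)
      if (ss < best_ss) { best_ss <- ss; fit <- cand }
      if (ss <= 1e-20 * max(sum(s^2), 1)) break
    }
  }
  if (is.null(fit)) return(invalid)
  cf <- coef(fit)
  res <- residuals(fit)
  sst <- sum((s - mean(s))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum(res^2) / sst)) else NA_real_
  valid <- is.finite(cf[["tau"]]) && cf[["tau"]] > 0 &&
    abs(cf[["A"]]) > floor_ && is.finite(r2)
  structure(list(tau = unname(cf[["tau"]]), amplitude = unname(cf[["A"]]),
                 y0 = if (fixed) y0_fixed else unname(cf[["y0"]]),
                 y0_fixed = fixed, r2 = r2, valid = valid),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$valid) cat("<decay_fit> invalid\n")
  else cat(sprintf("<decay_fit> tau = %.6g s, A = %.4g, y0 = %.4g%s, r2 = %.4f\n",
                   x$tau, x$amplitude, x$y0,
                   if (x$y0_fixed) " (fixed)" else "", x$r2))
  invisible(x)
}

#' Global biexponential fit across OFF-switching traces
#'
#' Fits `A_fast * exp(-k_fast t) + A_slow * exp(-k_slow t) + offset` to a
#' set of OFF-switching traces with the two rate constants shared across
#' all traces and the amplitudes/offsets free per trace — the analysis that
#' reveals (at least) two switchable species whose proportions change with
#' Ca2+.  Amplitudes are profiled out linearly at each candidate rate pair,
#' and the rate pair is optimised from several starts including the
#' degenerate single-rate solution, so the residual never exceeds the best
#' global single-exponential fit.
#'
#' @param traces List of [switching_trace()]s on identical time bases (each
#'   restricted to an OFF phase), typically with `meta$ca` labels.
#' @return A `biexp_fit`: `k_fast`, `k_slow` (1/s, `k_fast >= k_slow`),
#'   `amps` (matrix, one row per trace: `A_fast`, `A_slow`, `offset`),
#'   `residual` (sum of squared residuals), `residual_single` (same for the
#'   best global single-exponential).
#' @export
global_biexp <- function(traces) {
  if (length(traces) < 2L) stop("need at least 2 traces")
  t <- traces[[1]]$t - traces[[1]]$t[1]
  for (tr in traces) {
    ti <- tr$t - tr$t[1]
    if (length(ti) != length(t) || max(abs(ti - t)) > 1e-9 * max(t, 1))
      stop("traces are not on aligned time bases")
  }
  S <- vapply(traces, function(tr) tr$s, numeric(length(t)))
  ss_for <- function(basis) {
    tot <- 0
    amps <- matrix(0, ncol(S), ncol(basis))
    for (j in seq_len(ncol(S))) {
      fit <- lm.fit(basis, S[, j])
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      amps[j, ] <- cf
      tot <- tot + sum((S[, j] - basis %*% cf)^2)
    }
    list(ss = tot, amps = amps)
  }
  # global single-exponential (one shared rate)
  ss1 <- function(logk) ss_for(cbind(exp(-exp(logk) * t), 1))$ss
  t_max <- max(t)
  lo <- log(0.02 / t_max); hi <- log(2 * (length(t) - 1) / t_max)
  grid <- seq(lo, hi, length.out = 60)
  best <- grid[which.min(vapply(grid, ss1, numeric(1)))]
  opt1 <- optim(best, ss1, method = "Brent", lower = lo - 2, upper = hi + 2)
  k1 <- exp(opt1$par)
  res_single <- opt1$value
  # biexponential, rates shared
  ss2 <- function(th) ss_for(cbind(exp(-exp(th[1]) * t),
                                   exp(-exp(th[2]) * t), 1))$ss
  starts <- list(c(log(k1), log(k1) - 5),       # degenerate: equals single fit
                 c(log(k1) + log(5), log(k1)),
                 c(log(k1), log(k1) - log(5)),
                 c(log(k1) + log(10), log(k1) - log(10)))
  fits <- lapply(starts, function(st)
    optim(st, ss2, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14)))
  opt2 <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  k <- sort(exp(opt2$par), decreasing = TRUE)
  final <- ss_for(cbind(exp(-k[1] * t), exp(-k[2] * t), 1))
  amps <- final$amps
  colnames(amps) <- c("A_fast", "A_slow", "offset")
  structure(list(k_fast = k[1], k_slow = k[2], amps = amps,
                 residual = final$ss, residual_single = res_single),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> k_fast = %.4g, k_slow = %.4g 1/s; SS = %.4g (single-exp %.4g)\n",
              x$k_fast, x$k_slow, x$residual, x$residual_single))
  invisible(x)
}

#' Per-cycle photo-fatigue of a switching trace
#'
#' Measures the irreversible loss of switchable amplitude over repeated
#' OFF/ON cycles: the peak-to-trough amplitude of each cycle's 488-nm phase
#' is fitted with a geometric decay and the per-cycle fractional loss is
#' returned.
#'
#' @param trace A [switching_trace()] carrying its schedule attribute, with
#'   at least 3 full cycles.
#' @return Per-cycle fractional amplitude loss in \[0, 1).
#' @export
measure_fatigue <- function(trace) {
  schedule <- attr(trace, "schedule")
  if (is.null(schedule)) stop("trace must carry its illumination schedule")
  n_ph <- length(schedule$phases)
  wl <- vapply(schedule$phases, `[[`, numeric(1), "wavelength")
  cycle <- (trace$phase_id - 1L) %/% n_ph + 1L
  phase_index <- (trace$phase_id - 1L) %% n_ph + 1L
  off <- wl[phase_index] == 488
  cycles <- sort(unique(cycle[off]))
  if (length(cycles) < 3L) stop("need at least 3 full cycles")
  amp <- vapply(cycles, function(cc) {
    v <- trace$s[off & cycle == cc]
    diff(range(v))
  }, numeric(1))
  if (any(amp <= 0)) return(0)
  slope <- coef(lm(log(amp) ~ cycles))[2]
  loss <- 1 - exp(slope)
  max(0, min(loss, 1 - 1e-12))
}
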