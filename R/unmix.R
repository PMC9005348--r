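#' Frequency-domain photo-switching score of a trace
#'
#' Lock-in style detection of cycle-locked modulation: the per-frame signal
#' is mean-detrended, discrete-Fourier transformed, and the magnitude
#' at the cycle frequency (`n_cycles` periods over the record) is divided
#' by the summed magnitude of all non-zero (positive) frequencies.  A
#' switching pixel concentrates its spectral energy at the cycle frequency;
#' a constant trace scores 0, white noise about `1 / n_bins`.
#'
#' @param trace A [switching_trace()] (one sample per frame).
#' @param schedule Schedule defining `n_cycles`; defaults to the trace's
#'   own schedule attribute.
#' @return Score in \[0, 1\].
#' @export
fourier_switch_score <- function(trace, schedule = attr(trace, "schedule")) {
  if (is.null(schedule)) stop("a schedule is required to define the cycle frequency")
  if (schedule$n_cycles < 2L) stop("need at least 2 full cycles")
  drop(fourier_scores_matrix(matrix(trace$s, ncol = 1), schedule$n_cycles))
}

# Vectorised score over columns of M (one column per pixel).
fourier_scores_matrix <- function(M, n_cycles) {
  n <- nrow(M)
  if (n_cycles > n %/% 2)
    stop("cycle frequency above Nyquist: too few frames per cycle")
  res <- sweep(M, 2, colMeans(M))       # DC removal
  # constant traces leave only numerical dust after detrending; score 0
  scale_col <- apply(abs(M), 2, max)
  dust <- sqrt(colMeans(res^2)) <= 1e-12 * pmax(scale_col, .Machine$double.xmin)
  sp <- abs(mvfft(res))
  bins <- 2:(n %/% 2 + 1)            # positive non-zero frequencies
  num <- sp[n_cycles + 1L, , drop = TRUE]
  den <- colSums(sp[bins, , drop = FALSE])
  out <- ifelse(den > 0 & !dust, num / den, 0)
  pmin(pmax(out, 0), 1)
}

# Cycle-average the 488-nm OFF phases of a frame matrix [T, N].
# Returns list(t = within-phase frame times, M = [K, N] averaged frames).
off_cycle_average_matrix <- function(M, schedule) {
  ft <- frame_table(schedule)
  off <- ft$wavelength == 488
  cycles <- unique(ft$cycle[off])
  k_per <- sum(off & ft$cycle == cycles[1])
  acc <- matrix(0, k_per, ncol(M))
  for (cc in cycles) {
    sel <- which(off & ft$cycle == cc)
    acc <- acc + M[sel, , drop = FALSE]
  }
  list(t = ft$t_in_phase[off & ft$cycle == cycles[1]],
       M = acc / length(cycles))
}

#' Cycle-averaged OFF-switching trace of one pixel or ROI-mean signal
#'
#' Aligns the 488-nm phases of all cycles and averages them, reducing
#' per-pixel noise before decay fitting.
#'
#' @param stack An [image_time_series()].
#' @param x,y Pixel coordinates; or supply `signal` (per-frame vector) to
#'   average an arbitrary trace.
#' @param signal Optional per-frame signal overriding `x`, `y`.
#' @return A [switching_trace()] of the averaged OFF phase.
#' @export
off_cycle_average <- function(stack, x = NULL, y = NULL, signal = NULL) {
  s <- if (!is.null(signal)) signal else stack$frames[, y, x]
  avg <- off_cycle_average_matrix(matrix(s, ncol = 1), stack$schedule)
  switching_trace(avg$t, drop(avg$M), rep(1L, length(avg$t)),
                  meta = list(cycle_averaged = TRUE))
}

#' Classify pixels of a stack as photo-switching or not
#'
#' Applies the two classification measures per pixel: (1) the
#' frequency-domain switching score and (2) the coefficient of
#' determination r2 of a single-exponential fit to the cycle-averaged
#' 488-nm OFF phase.  A pixel enters the mask when its score is at least
#' `theta_f` and its r2 passes `theta_r` (with `r2_polarity = "high"`,
#' r2 >= theta_r; `"low"` selects r2 <= theta_r instead).  Fit failures
#' mark the pixel unswitchable (mask FALSE), never abort.
#'
#' @param stack An [image_time_series()].
#' @param theta_f Fourier-score threshold in \[0, 1\].
#' @param theta_r r2 threshold in \[0, 1\].
#' @param r2_polarity "high" (default) or "low".
#' @return A `switch_score_maps` object: `fourier_score` and `r2` matrices
#'   (`r2` is NA where no valid fit exists) and the logical `mask`.
#' @export
classify_pixels <- function(stack, theta_f = 0.2, theta_r = 0.8,
                            r2_polarity = c("high", "low")) {
  r2_polarity <- match.arg(r2_polarity)
  if (theta_f < 0 || theta_f > 1 || theta_r < 0 || theta_r > 1)
    stop("thresholds must lie in [0, 1]")
  d <- dim(stack$frames)
  h <- d[2]; w <- d[3]
  M <- matrix(stack$frames, d[1], h * w)
  fs <- fourier_scores_matrix(M, stack$schedule$n_cycles)
  avg <- off_cycle_average_matrix(M, stack$schedule)
  r2 <- rep(NA_real_, h * w)
  cand <- which(fs >= theta_f)
  for (j in cand) {
    fit <- fit_exp_decay(avg$t, avg$M[, j])
    if (fit$valid) r2[j] <- fit$r2
  }
  r2_ok <- !is.na(r2) & (if (r2_polarity == "high") r2 >= theta_r
                         else r2 <= theta_r)
  mask <- fs >= theta_f & r2_ok
  structure(list(fourier_score = matrix(fs, h, w),
                 r2 = matrix(r2, h, w),
                 mask = matrix(mask, h, w),
                 theta_f = theta_f, theta_r = theta_r,
                 r2_polarity = r2_polarity),
            class = "switch_score_maps")
}

#' @export
print.switch_score_maps <- function(x, ...) {
  cat(sprintf("<switch_score_maps> %d x %d px, %d masked (theta_f = %g, theta_r = %g, r2 %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$theta_f, x$theta_r,
              x$r2_polarity))
  invisible(x)
}

#' Reference offset from the saturated-Ca2+ sample
#'
#' Fits a free-offset exponential to the ROI-mean, cycle-averaged 488-nm
#' trace and returns the fitted offset y0.  The tomography analysis uses
#' the tube with the highest free Ca2+ as this reference and pins every
#' other pixel's fit to its offset.
#'
#' @param stack An [image_time_series()].
#' @param roi Either a logical `[H, W]` matrix or a list/vector with `x`,
#'   `y`, `r` defining a disk.
#' @return Fitted offset y0 (a.u.).  Errors if the reference fit is not
#'   valid — the reference must be reliable.
#' @export
reference_offset <- function(stack, roi) {
  d <- dim(stack$frames)
  m <- if (is.matrix(roi) && is.logical(roi)) roi else {
    roi <- as.list(roi)
    xy <- expand.grid(y = seq_len(d[2]), x = seq_len(d[3]))
    matrix((xy$x - roi$x)^2 + (xy$y - roi$y)^2 <= roi$r^2, d[2], d[3])
  }
  if (!any(m)) stop("ROI is empty")
  M <- matrix(stack$frames, d[1], d[2] * d[3])
  s <- rowMeans(M[, which(m), drop = FALSE])
  tr <- off_cycle_average(stack, signal = s)
  fit <- effective_tau(tr)
  if (!fit$valid)
    stop("reference offset fit invalid: ROI signal is not a usable decay")
  fit$y0
}

#' Fixed-offset decay-constant map
#'
#' For every masked pixel, fits the cycle-averaged 488-nm OFF phase with a
#' fixed-offset exponential (`y0` from [reference_offset()]) and returns
#' the per-pixel decay constant and amplitude; NA where the fit is invalid.
#'
#' @param stack An [image_time_series()].
#' @param mask Logical `[H, W]` matrix (e.g. from [classify_pixels()]).
#' @param y0 Fixed offset, a.u.
#' @return A `tau_map`: list with `tau` and `amplitude` `[H, W]` matrices.
#' @export
fit_pixel_kinetics <- function(stack, mask, y0) {
  if (!is.finite(y0)) stop("`y0` must be finite")
  d <- dim(stack$frames)
  stopifnot(is.logical(mask), all(dim(mask) == d[2:3]))
  M <- matrix(stack$frames, d[1], d[2] * d[3])
  avg <- off_cycle_average_matrix(M, stack$schedule)
  tau <- matrix(NA_real_, d[2], d[3])
  amp <- matrix(NA_real_, d[2], d[3])
  for (j in which(mask)) {
    fit <- fit_exp_decay(avg$t, avg$M[, j], y0_fixed = y0)
    if (fit$valid) {
      tau[j] <- fit$tau
      amp[j] <- fit$amplitude
    }
  }
  structure(list(tau = tau, amplitude = amp, y0 = y0), class = "tau_map")
}

#' @export
print.tau_map <- function(x, ...) {
  ok <- is.finite(x$tau)
  cat(sprintf("<tau_map> %d px fitted; tau in [%.4g, %.4g] s\n", sum(ok),
              if (any(ok)) min(x$tau[ok]) else NA,
              if (any(ok)) max(x$tau[ok]) else NA))
  invisible(x)
}

#' Proportional ON-OFF difference image
#'
#' `(on - off) / on` per pixel; pixels with `on <= floor` are set to 0.
#' This is the raster-scan mesoscopy unmixing step that isolates
#' switchable signal from static background.
#'
#' @param on_img,off_img Matrices of equal shape.
#' @param floor Pixels with ON signal at or below this value return 0.
#' @return Matrix of proportional differences.
#' @export
on_off_difference <- function(on_img, off_img, floor = 0) {
  if (!all(dim(on_img) == dim(off_img)))
    stop("ON and OFF images must have the same shape")
  out <- matrix(0, nrow(on_img), ncol(on_img))
  ok <- on_img > floor
  out[ok] <- (on_img[ok] - off_img[ok]) / on_img[ok]
  out
}
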