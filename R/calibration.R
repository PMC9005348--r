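#' Dose-response calibration of decay constant versus Ca2+
#'
#' Fits the four-parameter logistic in log10 concentration,
#'
#'   tau(c) = tau_min + (tau_max - tau_min) / (1 + 10^((c - log_ec50) * hill_slope))
#'
#' with `c = log10(ca)`, linking the OFF-switching decay constant to free
#' Ca2+.  With `fix_from = c(ca_lo, ca_hi)`, the endpoints are pinned to
#' the measured tau at those two concentrations (the tomography analysis
#' fixes them at the 0 and 39 uM samples so the fit converges) and only
#' `log_ec50` and `hill_slope` remain free.  A `ca` of 0 is representable
#' only as a fixed `tau_max` endpoint; it cannot enter the free fit.
#'
#' @param tau_by_ca Data frame with columns `ca` (uM) and `tau` (s).
#' @param fix_from Optional length-2 vector: the concentrations whose
#'   measured tau pin `tau_max` (first, lowest ca) and `tau_min` (second,
#'   highest ca).
#' @return A `calibration_model`: `tau_max`, `tau_min`, `log_ec50`,
#'   `hill_slope`, `endpoints_fixed`, plus the fitted `ca_endpoints` used
#'   when inverting out-of-range values.
#' @export
fit_dose_response <- function(tau_by_ca, fix_from = NULL) {
  stopifnot(all(c("ca", "tau") %in% names(tau_by_ca)))
  df <- tau_by_ca[is.finite(tau_by_ca$tau), , drop = FALSE]
  if (any(df$ca == 0) && is.null(fix_from))
    stop("ca = 0 is only representable as a fixed tau_max endpoint; supply fix_from")
  pos <- df[df$ca > 0, , drop = FALSE]
  if (nrow(pos) < 4L) stop("need >= 4 positive concentration points")
  if (max(pos$ca) / min(pos$ca) <= 10)
    stop("concentration grid must span more than one decade")
  if (diff(range(df$tau)) < 1e-10 * max(abs(df$tau)))
    stop("flat tau response: hill_slope unidentifiable")
  cc <- log10(pos$ca)
  tau <- pos$tau
  fixed <- !is.null(fix_from)
  fit <- tryCatch({
    if (fixed) {
      stopifnot(length(fix_from) == 2L)
      pick <- function(ca0) {
        v <- df$tau[abs(df$ca - ca0) < 1e-9 * max(ca0, 1)]
        if (!length(v)) stop("fix_from concentration ", ca0, " not in table")
        mean(v)
      }
      tau_max <- pick(fix_from[1]); tau_min <- pick(fix_from[2])
      dd <- data.frame(cc = cc, tau = tau)
      mid <- (max(tau) + min(tau)) / 2
      cc_mid <- cc[which.min(abs(tau - mid))]
      slope_sign <- if (cor(cc, tau) < 0) 1 else -1
      fitf <- NULL
      for (st in list(list(e = cc_mid, h = slope_sign),
                      list(e = median(cc), h = slope_sign),
                      list(e = cc_mid, h = 2 * slope_sign))) {
        fitf <- tryCatch(minpack.lm::nlsLM(
          tau ~ tau_min + (tau_max - tau_min) /
            (1 + 10^((cc - log_ec50) * hill_slope)),
          data = dd, start = list(log_ec50 = st$e, hill_slope = st$h),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
          error = function(e) NULL)
        if (!is.null(fitf)) break
      }
      if (is.null(fitf)) stop("singular fit from all starts")
      fitf
    } else {
      rng <- diff(range(tau))
      mid <- (max(tau) + min(tau)) / 2
      cc_mid <- cc[which.min(abs(tau - mid))]
      slope_sign <- if (cor(cc, tau) < 0) 1 else -1
      dd <- data.frame(cc = cc, tau = tau)
      fit <- NULL
      for (st in list(list(e = cc_mid, h = slope_sign),
                      list(e = median(cc), h = slope_sign),
                      list(e = cc_mid, h = 2 * slope_sign))) {
        fit <- tryCatch(minpack.lm::nlsLM(
          tau ~ tmin + (tmax - tmin) / (1 + 10^((cc - log_ec50) * hill_slope)),
          data = dd,
          start = list(tmin = max(min(tau) - 0.05 * rng, 1e-6),
                       tmax = max(tau) + 0.05 * rng,
                       log_ec50 = st$e, hill_slope = st$h),
          lower = c(1e-12, 1e-12, -Inf, -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) stop("singular fit from all starts")
      fit
    }
  }, error = function(e)
    stop("dose-response fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  if (!fixed) { tau_min <- cf[["tmin"]]; tau_max <- cf[["tmax"]] }
  log_ec50 <- cf[["log_ec50"]]; hill_slope <- cf[["hill_slope"]]
  if (tau_max < tau_min) {   # canonical form: tau_max > tau_min, same curve
    tmp <- tau_max; tau_max <- tau_min; tau_min <- tmp
    hill_slope <- -hill_slope
  }
  if (!(tau_max > tau_min) || tau_min <= 0 || hill_slope == 0)
    stop("dose-response fit degenerate (tau_max <= tau_min or zero slope)")
  ca_lo <- if (fixed) fix_from[1] else min(pos$ca)
  ca_hi <- if (fixed) fix_from[2] else max(pos$ca)
  structure(list(tau_max = unname(tau_max), tau_min = unname(tau_min),
                 log_ec50 = unname(log_ec50), hill_slope = unname(hill_slope),
                 endpoints_fixed = fixed,
                 ca_endpoints = c(ca_lo, ca_hi)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> tau: %.4g -> %.4g s, log10 EC50 = %.4g (EC50 = %.4g uM), Hill slope = %.4g%s\n",
              x$tau_max, x$tau_min, x$log_ec50, 10^x$log_ec50, x$hill_slope,
              if (x$endpoints_fixed) " [endpoints fixed]" else ""))
  invisible(x)
}

#' Predict tau from a calibration model
#' @param object A `calibration_model`.
#' @param ca Free Ca2+ concentrations, uM (> 0).
#' @param ... Unused.
#' @return Predicted decay constants, s.
#' @export
predict.calibration_model <- function(object, ca, ...) {
  cc <- log10(ca)
  object$tau_min + (object$tau_max - object$tau_min) /
    (1 + 10^((cc - object$log_ec50) * object$hill_slope))
}

#' Invert a calibration model: decay constant to relative Ca2+
#'
#' Closed-form inversion of the dose-response curve.  Values of tau outside
#' the open interval (`tau_min`, `tau_max`) clamp to the corresponding
#' calibration endpoint concentration, with the `out_of_range` attribute
#' flagging them.
#'
#' @param calib A `calibration_model`.
#' @param tau Decay constants, s (vectorised).
#' @return Ca2+ concentrations (uM, relative), with logical attribute
#'   `out_of_range`.
#' @export
invert_tau <- function(calib, tau) {
  stopifnot(inherits(calib, "calibration_model"))
  lo_ca <- calib$ca_endpoints[1]; hi_ca <- calib$ca_endpoints[2]
  # tau_max is reached at the low-ca end when hill_slope > 0, else high-ca
  max_side_ca <- if (calib$hill_slope > 0) lo_ca else hi_ca
  min_side_ca <- if (calib$hill_slope > 0) hi_ca else lo_ca
  out <- numeric(length(tau))
  oor <- logical(length(tau))
  interior <- is.finite(tau) & tau > calib$tau_min & tau < calib$tau_max
  x <- (calib$tau_max - calib$tau_min) / (tau[interior] - calib$tau_min) - 1
  out[interior] <- 10^(calib$log_ec50 + log10(x) / calib$hill_slope)
  hi_t <- is.finite(tau) & tau >= calib$tau_max
  lo_t <- is.finite(tau) & tau <= calib$tau_min
  out[hi_t] <- max_side_ca; oor[hi_t] <- TRUE
  out[lo_t] <- min_side_ca; oor[lo_t] <- TRUE
  out[!is.finite(tau)] <- NA_real_
  attr(out, "out_of_range") <- oor
  out
}

#' Fit the Hill binding isotherm to a titration table
#'
#' Least-squares fit of
#' `signal = base + (sat - base) * ca^n / (kd^n + ca^n)`
#' returning the dissociation constant, Hill coefficient and the two
#' asymptotic signals with standard errors from the linearised covariance.
#' Works for increasing or decreasing responses (`sat` may be below
#' `base`).
#'
#' @param titration A `titration_table` (or data frame with `ca`,
#'   `mean_signal`).
#' @return List with `kd` (uM), `hill_n`, `sat_signal`, `base_signal` and
#'   `se` (named vector of standard errors).
#' @export
fit_binding <- function(titration) {
  stopifnot(all(c("ca", "mean_signal") %in% names(titration)))
  df <- data.frame(ca = titration$ca, s = titration$mean_signal)
  if (nrow(df) < 5L) stop("need >= 5 titration points")
  if (diff(range(df$s)) < 1e-12 * max(abs(df$s), 1))
    stop("no transition in range: binding parameters unidentifiable")
  base0 <- df$s[which.min(df$ca)]
  sat0 <- df$s[which.max(df$ca)]
  mid <- (base0 + sat0) / 2
  kd0 <- df$ca[which.min(abs(df$s - mid))]
  if (kd0 <= 0) kd0 <- median(df$ca[df$ca > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ base + (sat - base) * ca^n / (kd^n + ca^n),
      data = df,
      start = list(base = base0, sat = sat0, kd = kd0, n = 1),
      lower = c(-Inf, -Inf, 1e-9, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12)),
    error = function(e)
      stop("binding fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  if (cf[["kd"]] > max(df$ca) * 10 || cf[["kd"]] < min(df$ca[df$ca > 0]) / 10)
    stop("no transition in range: fitted Kd outside the sampled concentrations")
  list(kd = unname(cf[["kd"]]), hill_n = unname(cf[["n"]]),
       sat_signal = unname(cf[["sat"]]), base_signal = unname(cf[["base"]]),
       se = c(kd = unname(se[["kd"]]), hill_n = unname(se[["n"]]),
              sat_signal = unname(se[["sat"]]),
              base_signal = unname(se[["base"]])))
}
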