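#' Photophysical and binding parameters of one sensor variant
#'
#' Bundles the equilibrium Ca2+ binding parameters with the photo-switching
#' rate constants of a reversibly switchable Ca2+ indicator.  The bound
#' state photo-switches; the Ca2+-free state is dim (a fraction `eps_free`
#' of the bound-state brightness) and does not switch.  OFF-switching under
#' 488-nm light is modelled as a mixture of a fast and a slow switchable
#' species; rates scale linearly with illumination intensity.
#'
#' @param kd Dissociation constant, uM.  Default 72 uM (an ER-affinity
#'   variant).
#' @param hill_n Hill coefficient of the binding isotherm (dimensionless).
#' @param brightness Bound-state signal scale, arbitrary units.
#' @param eps_free Relative brightness of the Ca2+-free state, as a fraction
#'   of `brightness` (0..1).
#' @param sigma_fast,sigma_slow OFF-switching rate per unit 488-nm intensity
#'   for the fast and slow switchable species, 1/s per a.u.  Must satisfy
#'   `sigma_fast >= sigma_slow >= 0`.
#' @param sigma_on ON-switching rate per unit 405/420-nm intensity, 1/s per
#'   a.u.
#' @param fatigue_per_cycle Fractional irreversible loss of switchable
#'   signal per full OFF/ON cycle (0 <= x < 1).
#' @param dark_offset Non-modulating residual signal, a.u.
#'
#' @return An object of class `sensor_model` (a named list).
#' @examples
#' s <- sensor_model()
#' s$kd
#' @export
sensor_model <- function(kd = 72, hill_n = 1, brightness = 1,
                         eps_free = 0.1, sigma_fast = 3.0, sigma_slow = 0.4,
                         sigma_on = 5.0, fatigue_per_cycle = 0.005,
                         dark_offset = 0) {
  stopifnot(is.numeric(kd), length(kd) == 1L)
  if (!(kd > 0)) stop("`kd` must be positive")
  if (!(hill_n > 0)) stop("`hill_n` must be positive")
  if (eps_free < 0 || eps_free > 1) stop("`eps_free` must be in [0, 1]")
  if (!(sigma_fast >= sigma_slow && sigma_slow >= 0))
    stop("need sigma_fast >= sigma_slow >= 0")
  if (sigma_on < 0) stop("`sigma_on` must be >= 0")
  if (fatigue_per_cycle < 0 || fatigue_per_cycle >= 1)
    stop("`fatigue_per_cycle` must be in [0, 1)")
  structure(list(kd = kd, hill_n = hill_n, brightness = brightness,
                 eps_free = eps_free, sigma_fast = sigma_fast,
                 sigma_slow = sigma_slow, sigma_on = sigma_on,
                 fatigue_per_cycle = fatigue_per_cycle,
                 dark_offset = dark_offset),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat("<sensor_model>\n")
  cat(sprintf("  Kd = %g uM, Hill n = %g\n", x$kd, x$hill_n))
  cat(sprintf("  brightness = %g a.u. (free state %g%%), dark offset = %g\n",
              x$brightness, 100 * x$eps_free, x$dark_offset))
  cat(sprintf("  sigma_fast = %g, sigma_slow = %g, sigma_on = %g (1/s per a.u.)\n",
              x$sigma_fast, x$sigma_slow, x$sigma_on))
  cat(sprintf("  fatigue = %g per cycle\n", x$fatigue_per_cycle))
  invisible(x)
}

#' Build a sensor model from a plain list (config file contents)
#'
#' @param x Named list with any subset of the `sensor_model()` arguments.
#' @return A `sensor_model`.
#' @export
sensor_from_list <- function(x) {
  if (inherits(x, "sensor_model")) return(x)
  do.call(sensor_model, x[intersect(names(x), names(formals(sensor_model)))])
}

#' Equilibrium bound fraction from the Hill isotherm
#'
#' Fraction of sensor molecules with Ca2+ bound at equilibrium,
#' `ca^n / (kd^n + ca^n)`.
#'
#' @param ca Free Ca2+ concentration, uM (vectorised, all >= 0).
#' @param kd Dissociation constant, uM (> 0).
#' @param n Hill coefficient (> 0).
#' @return Bound fraction in \[0, 1\], same length as `ca`.
#' @examples
#' hill_fraction(500, 72, 1)  # ~0.874: mostly bound at ER-like Ca2+
#' hill_fraction(72, 72, 2)   # 0.5 at ca = Kd for any n
#' @export
hill_fraction <- function(ca, kd, n) {
  if (any(!is.finite(ca)) || any(ca < 0)) stop("`ca` must be finite and >= 0")
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be positive")
  if (!is.finite(n) || n <= 0) stop("`n` must be positive")
  # computed in log space for large n stability
  r <- (ca / kd)^n
  r / (1 + r)
}
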