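#' Pulsed 488/420-nm illumination schedule
#'
#' Defines the time base of every simulated trace and image stack: an
#' ordered list of illumination phases, repeated for `n_cycles` cycles.
#' Each phase delivers `n_pulses` pulses of one wavelength at `pulse_rate`
#' Hz; consecutive `pulses_per_frame` pulses are averaged into one recorded
#' frame (the tomography acquisition averaged over three laser pulses).
#'
#' @param phases List of phases; each phase is a named list/vector with
#'   `wavelength` (nm, one of 488, 420, 405), `intensity` (a.u., > 0),
#'   `n_pulses` (count >= 1) and `pulse_rate` (Hz, > 0).
#' @param n_cycles Number of cycles (>= 1).
#' @param pulses_per_frame Averaging window; must divide every phase's
#'   `n_pulses` so frames never straddle a phase boundary.
#' @return An `illumination_schedule` object.
#' @examples
#' # the tomography scheme: ten cycles of 120 pulses 488 nm + 120 pulses 420 nm
#' sch <- oa_tomography_schedule()
#' n_frames(sch)
#' @export
illumination_schedule <- function(phases, n_cycles = 1L, pulses_per_frame = 1L) {
  if (length(phases) < 1L) stop("schedule needs at least one phase")
  phases <- lapply(phases, function(p) {
    p <- as.list(p)
    need <- c("wavelength", "intensity", "n_pulses", "pulse_rate")
    if (!all(need %in% names(p)))
      stop("each phase needs fields: ", paste(need, collapse = ", "))
    if (!p$wavelength %in% c(488, 420, 405))
      stop("wavelength must be one of 488, 420, 405 nm")
    if (p$intensity <= 0) stop("phase intensity must be > 0")
    if (p$n_pulses < 1) stop("n_pulses must be >= 1")
    if (p$pulse_rate <= 0) stop("pulse_rate must be > 0")
    p[need]
  })
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (pulses_per_frame < 1) stop("pulses_per_frame must be >= 1")
  for (p in phases)
    if (p$n_pulses %% pulses_per_frame != 0)
      stop("pulses_per_frame (", pulses_per_frame,
           ") must divide every phase's n_pulses (got ", p$n_pulses, ")")
  structure(list(phases = phases, n_cycles = as.integer(n_cycles),
                 pulses_per_frame = as.integer(pulses_per_frame)),
            class = "illumination_schedule")
}

#' @export
print.illumination_schedule <- function(x, ...) {
  cat("<illumination_schedule>", x$n_cycles, "cycle(s) of:\n")
  for (p in x$phases)
    cat(sprintf("  %d nm, I = %g a.u., %d pulses @ %g Hz\n",
                p$wavelength, p$intensity, p$n_pulses, p$pulse_rate))
  cat(sprintf("  %d pulse(s)/frame -> %d frames total\n",
              x$pulses_per_frame, n_frames(x)))
  invisible(x)
}

#' Default optoacoustic tomography schedule
#'
#' Ten cycles of 120 pulses at 488 nm followed by 120 pulses at 420 nm,
#' 10-Hz pulsing, frames averaged over three laser pulses.
#'
#' @param n_cycles,n_pulses,pulse_rate,pulses_per_frame,intensity Overrides
#'   of the default acquisition parameters.
#' @return An `illumination_schedule`.
#' @export
oa_tomography_schedule <- function(n_cycles = 10L, n_pulses = 120L,
                                   pulse_rate = 10, pulses_per_frame = 3L,
                                   intensity = 1) {
  illumination_schedule(
    phases = list(
      list(wavelength = 488, intensity = intensity, n_pulses = n_pulses,
           pulse_rate = pulse_rate),
      list(wavelength = 420, intensity = intensity, n_pulses = n_pulses,
           pulse_rate = pulse_rate)),
    n_cycles = n_cycles, pulses_per_frame = pulses_per_frame)
}

#' Single OFF-switching decay schedule (spectrometer geometry)
#'
#' One 488-nm phase: the sample starts fully ON and is switched off while
#' its signal is recorded pulse by pulse.
#'
#' @param n_pulses,pulse_rate,intensity Acquisition parameters.
#' @return An `illumination_schedule`.
#' @export
spectrometer_schedule <- function(n_pulses = 120L, pulse_rate = 10,
                                  intensity = 1) {
  illumination_schedule(
    phases = list(list(wavelength = 488, intensity = intensity,
                       n_pulses = n_pulses, pulse_rate = pulse_rate)),
    n_cycles = 1L, pulses_per_frame = 1L)
}

#' Total number of recorded frames in a schedule
#' @param schedule An `illumination_schedule`.
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "illumination_schedule"))
  pulses <- sum(vapply(schedule$phases, `[[`, numeric(1), "n_pulses"))
  as.integer(schedule$n_cycles * pulses / schedule$pulses_per_frame)
}

# Expand a schedule to one row per pulse.  Time starts at 0; the first pulse
# of each phase is sampled at the phase start (no decay yet applied).
pulse_table <- function(schedule) {
  ph <- schedule$phases
  n_ph <- length(ph)
  rows <- vector("list", schedule$n_cycles * n_ph)
  t_off <- 0
  pid <- 0L
  k <- 0L
  for (cyc in seq_len(schedule$n_cycles)) {
    for (i in seq_len(n_ph)) {
      p <- ph[[i]]
      pid <- pid + 1L
      k <- k + 1L
      tt <- t_off + (seq_len(p$n_pulses) - 1) / p$pulse_rate
      rows[[k]] <- data.frame(
        t = tt, t_in_phase = tt - t_off, phase_id = pid, cycle = cyc,
        phase_index = i, wavelength = p$wavelength, intensity = p$intensity)
      t_off <- t_off + p$n_pulses / p$pulse_rate
    }
  }
  do.call(rbind, rows)
}

# One row per recorded frame: frame time = mean pulse time in the window.
frame_table <- function(schedule) {
  pt <- pulse_table(schedule)
  ppf <- schedule$pulses_per_frame
  frame <- (seq_len(nrow(pt)) - 1L) %/% ppf + 1L
  agg <- function(v) if (ppf == 1L) v else tapply(v, frame, mean)
  first <- function(v) if (ppf == 1L) v else tapply(v, frame, `[`, 1L)
  data.frame(frame = unique(frame),
             t = as.numeric(agg(pt$t)),
             t_in_phase = as.numeric(agg(pt$t_in_phase)),
             phase_id = as.integer(first(pt$phase_id)),
             cycle = as.integer(first(pt$cycle)),
             phase_index = as.integer(first(pt$phase_index)),
             wavelength = as.integer(first(pt$wavelength)),
             intensity = as.numeric(first(pt$intensity)),
             row.names = NULL)
}

#' Build a schedule from a plain list (config file contents)
#' @param x Named list with `phases`, `n_cycles`, `pulses_per_frame`.
#' @return An `illumination_schedule`.
#' @export
schedule_from_list <- function(x) {
  if (inherits(x, "illumination_schedule")) return(x)
  phases <- x$phases
  if (is.data.frame(phases))   # JSON readers simplify the phase list
    phases <- lapply(seq_len(nrow(phases)), function(i) as.list(phases[i, ]))
  illumination_schedule(phases = phases,
                        n_cycles = x$n_cycles %||% 1L,
                        pulses_per_frame = x$pulses_per_frame %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
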