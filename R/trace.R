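#' Construct a switching trace
#'
#' A `switching_trace` is a data frame with columns `t` (seconds, strictly
#' increasing), `s` (signal, a.u.) and `phase_id` (per-sample illumination
#' phase index), optionally carrying the generating schedule and free-text
#' metadata (e.g. the Ca2+ concentration) as attributes.
#'
#' @param t Sample times, s.
#' @param s Signal values, a.u.
#' @param phase_id Integer phase index per sample.
#' @param schedule Optional `illumination_schedule`.
#' @param meta Optional named list of metadata (`ca` in uM, `source`, ...).
#' @return A `switching_trace`.
#' @export
switching_trace <- function(t, s, phase_id = rep(1L, length(t)),
                            schedule = NULL, meta = list()) {
  if (length(t) != length(s) || length(t) != length(phase_id))
    stop("t, s and phase_id must have equal length")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  if (any(!is.finite(s))) stop("`s` must be finite")
  out <- data.frame(t = as.numeric(t), s = as.numeric(s),
                    phase_id = as.integer(phase_id))
  attr(out, "schedule") <- schedule
  attr(out, "meta") <- meta
  class(out) <- c("switching_trace", "data.frame")
  out
}

#' Restrict a trace to the samples of one (or more) phases
#' @param trace A `switching_trace`.
#' @param phase_id Phase index or indices to keep.
#' @param rezero Shift times so the first kept sample is at t = 0.
#' @return A `switching_trace`.
#' @export
trace_phase <- function(trace, phase_id, rezero = TRUE) {
  keep <- trace$phase_id %in% phase_id
  if (!any(keep)) stop("no samples in phase(s) ", paste(phase_id, collapse = ","))
  t <- trace$t[keep]
  switching_trace(if (rezero) t - t[1] else t, trace$s[keep],
                  trace$phase_id[keep], schedule = attr(trace, "schedule"),
                  meta = attr(trace, "meta"))
}

#' Write / read a trace as CSV
#'
#' CSV with header `t_s,signal,phase_id`.
#'
#' @param trace A `switching_trace`.
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `switching_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t_s = trace$t, signal = trace$s, phase_id = trace$phase_id)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t_s", "signal", "phase_id")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  switching_trace(df$t_s, df$signal, df$phase_id,
                  meta = list(source = path))
}
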