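#' Phantom layout for synthetic tomography stacks
#'
#' Describes a tube phantom: circular regions of either sensor (at a stated
#' free Ca2+ concentration) or blood (static absorber) embedded in a
#' non-absorbing background, illuminated from one side with exponentially
#' attenuating fluence.
#'
#' @param height,width Image size, pixels.
#' @param pixel_size Pixel pitch, mm.
#' @param regions List of regions; each a list with `center` (c(x, y),
#'   pixel coordinates, origin top-left), `radius` (pixels), `kind`
#'   ("sensor" or "blood"), `ca` (uM, sensor only) and `strength` (a.u.).
#' @param mu_eff Effective attenuation coefficient, 1/mm (>= 0).
#' @param illum_side Side the light enters from: "top", "bottom", "left" or
#'   "right".
#' @return A `phantom_layout`.
#' @export
phantom_layout <- function(height = 128L, width = 128L, pixel_size = 0.1,
                           regions, mu_eff = 0.1, illum_side = "top") {
  illum_side <- match.arg(illum_side, c("top", "bottom", "left", "right"))
  if (mu_eff < 0) stop("`mu_eff` must be >= 0")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  for (r in regions) {
    if (!all(c("center", "radius", "kind", "strength") %in% names(r)))
      stop("each region needs center, radius, kind, strength")
    if (!r$kind %in% c("sensor", "blood")) stop("region kind must be sensor or blood")
    if (r$radius <= 0) stop("region radii must be > 0")
    if (r$center[1] - r$radius < 1 || r$center[1] + r$radius > width ||
        r$center[2] - r$radius < 1 || r$center[2] + r$radius > height)
      stop("region extends outside the image")
    if (r$kind == "sensor" && (is.null(r$ca) || !is.finite(r$ca) || r$ca < 0))
      stop("sensor regions need finite ca >= 0")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 pixel_size = pixel_size, regions = regions,
                 mu_eff = mu_eff, illum_side = illum_side),
            class = "phantom_layout")
}

#' Default four-concentration tube phantom
#'
#' Four sensor tubes at 0.35, 1.35, 5.2 and 39 uM free Ca2+ plus two blood
#' tubes, 128 x 128 pixels at 0.1 mm/pixel, illuminated from the top — the
#' synthetic counterpart of the four-concentration tube experiment.  The
#' sensor tubes sit side by side at the same depth (as in the real phantom,
#' where the tubes lie behind a common agar layer) so their decay constants
#' are compared at equal fluence; the blood tubes sit deeper.
#'
#' @param mu_eff Effective attenuation, 1/mm.
#' @param radius Tube radius, pixels.
#' @return A `phantom_layout`.
#' @export
default_phantom_layout <- function(mu_eff = 0.1, radius = 8) {
  phantom_layout(
    height = 128L, width = 128L, pixel_size = 0.1,
    regions = list(
      list(center = c(20, 40), radius = radius, kind = "sensor", ca = 0.35,
           strength = 1),
      list(center = c(48, 40), radius = radius, kind = "sensor", ca = 1.35,
           strength = 1),
      list(center = c(76, 40), radius = radius, kind = "sensor", ca = 5.2,
           strength = 1),
      list(center = c(104, 40), radius = radius, kind = "sensor", ca = 39,
           strength = 1),
      list(center = c(48, 88), radius = radius, kind = "blood",
           strength = 1.5),
      list(center = c(104, 88), radius = radius, kind = "blood",
           strength = 1.5)),
    mu_eff = mu_eff, illum_side = "top")
}

# Logical mask of one circular region.
region_mask <- function(layout, region) {
  xy <- expand.grid(y = seq_len(layout$height), x = seq_len(layout$width))
  m <- (xy$x - region$center[1])^2 + (xy$y - region$center[2])^2 <=
    region$radius^2
  matrix(m, layout$height, layout$width)
}

#' Ground-truth region maps of a phantom layout
#'
#' @param layout A [phantom_layout()].
#' @return List with `sensor` and `blood` logical masks and `region_id`
#'   (integer matrix, 0 = background).
#' @export
layout_truth_masks <- function(layout) {
  h <- layout$height; w <- layout$width
  sensor <- matrix(FALSE, h, w); blood <- matrix(FALSE, h, w)
  region_id <- matrix(0L, h, w)
  for (i in seq_along(layout$regions)) {
    r <- layout$regions[[i]]
    m <- region_mask(layout, r)
    region_id[m] <- i
    if (r$kind == "sensor") sensor <- sensor | m else blood <- blood | m
  }
  list(sensor = sensor, blood = blood, region_id = region_id)
}

# Fluence map: exp(-mu_eff * depth), depth measured from the illuminated
# side along the image axis.
fluence_map <- function(layout) {
  h <- layout$height; w <- layout$width; ps <- layout$pixel_size
  depth_row <- switch(layout$illum_side,
                      top = (seq_len(h) - 1) * ps,
                      bottom = (h - seq_len(h)) * ps,
                      left = NULL, right = NULL)
  if (!is.null(depth_row)) {
    matrix(exp(-layout$mu_eff * depth_row), h, w)
  } else {
    depth_col <- switch(layout$illum_side,
                        left = (seq_len(w) - 1) * ps,
                        right = (w - seq_len(w)) * ps)
    matrix(exp(-layout$mu_eff * depth_col), h, w, byrow = TRUE)
  }
}

#' Image time-series container
#'
#' @param frames Numeric array `[T, H, W]`.
#' @param schedule The [illumination_schedule()] that produced the frames.
#' @param layout_truth Optional generating [phantom_layout()].
#' @param meta Optional named list of metadata.
#' @return An `image_time_series`.
#' @export
image_time_series <- function(frames, schedule, layout_truth = NULL,
                              meta = list()) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  nf <- n_frames(schedule)
  if (dim(frames)[1] != nf)
    stop("frame count (", dim(frames)[1], ") does not match schedule (",
         nf, ")")
  if (any(!is.finite(frames))) stop("frames must be finite")
  structure(list(frames = frames, schedule = schedule,
                 layout_truth = layout_truth, meta = meta),
            class = "image_time_series")
}

#' @export
print.image_time_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_time_series> %d frames of %d x %d px%s\n", d[1], d[2],
              d[3], if (!is.null(x$layout_truth)) " (with ground truth)" else ""))
  invisible(x)
}

#' Extract the trace of one pixel
#' @param stack An [image_time_series()].
#' @param x,y Pixel coordinates (column, row), origin top-left.
#' @return A [switching_trace()].
#' @export
pixel_trace <- function(stack, x, y) {
  ft <- frame_table(stack$schedule)
  switching_trace(ft$t, stack$frames[, y, x], ft$phase_id,
                  schedule = stack$schedule, meta = list(x = x, y = y))
}

#' Synthetic fluorescence titration
#'
#' Equilibrium signal versus free Ca2+:
#' `dark_offset + brightness * (eps_free + (1 - eps_free) * hill_fraction(ca))`
#' with multiplicative Gaussian noise of coefficient of variation
#' `noise_cv` per replicate.
#'
#' @param sensor A [sensor_model()].
#' @param ca_grid Free Ca2+ concentrations, uM, strictly increasing.
#' @param n_rep Replicates per concentration.
#' @param noise_cv Coefficient of variation of the replicate noise.
#' @param seed Integer seed (bit-reproducible output).
#' @return A `titration_table` data frame with columns `ca`, `mean_signal`,
#'   `sd_signal`, `n_rep`; the generating sensor is attached as attribute
#'   `truth`.
#' @export
make_titration <- function(sensor, ca_grid, n_rep = 3L, noise_cv = 0.02,
                           seed = NULL) {
  if (length(ca_grid) < 1L) stop("`ca_grid` must be non-empty")
  if (any(diff(ca_grid) <= 0)) stop("`ca_grid` must be strictly increasing")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  mu <- sensor$dark_offset + sensor$brightness *
    (sensor$eps_free + (1 - sensor$eps_free) *
       hill_fraction(ca_grid, sensor$kd, sensor$hill_n))
  sim <- function() {
    reps <- vapply(mu, function(m)
      m * (1 + rnorm(n_rep, 0, noise_cv)), numeric(n_rep))
    reps <- matrix(reps, nrow = n_rep)
    data.frame(ca = ca_grid, mean_signal = colMeans(reps),
               sd_signal = apply(reps, 2, sd), n_rep = as.integer(n_rep))
  }
  out <- if (noise_cv == 0) {
    data.frame(ca = ca_grid, mean_signal = mu, sd_signal = 0,
               n_rep = as.integer(n_rep))
  } else if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  attr(out, "truth") <- sensor
  class(out) <- c("titration_table", "data.frame")
  out
}

#' Synthetic spectrometer decay series
#'
#' For each concentration, `n_rep` OFF-switching decays are simulated,
#' averaged, and normalised to the maximum of the averaged trace — the
#' six-decays-averaged-then-normalised protocol of the optoacoustic
#' spectrometer measurements.
#'
#' @param sensor A [sensor_model()].
#' @param ca_list Free Ca2+ concentrations, uM.
#' @param n_rep Decays averaged per concentration (default 6).
#' @param schedule Illumination schedule (default a single 488-nm decay).
#' @param noise_sd Per-frame additive noise of each individual decay, a.u.
#' @param seed Integer seed; replicate seeds are fanned out
#'   deterministically.
#' @return Named list of max-normalised [switching_trace()]s (names = ca),
#'   each with `meta$ca` set.
#' @export
make_spectrometer_series <- function(sensor, ca_list, n_rep = 6L,
                                     schedule = spectrometer_schedule(),
                                     noise_sd = 0, seed = NULL) {
  if (length(ca_list) < 1L) stop("`ca_list` must be non-empty")
  out <- vector("list", length(ca_list))
  names(out) <- as.character(ca_list)
  for (i in seq_along(ca_list)) {
    reps <- lapply(seq_len(n_rep), function(j) {
      sj <- if (is.null(seed)) NULL else
        stage_seed(seed, paste0("spectro", i, "_", j))
      simulate_trace(sensor, schedule, ca_list[i], noise_sd = noise_sd,
                     seed = sj)
    })
    s_avg <- rowMeans(vapply(reps, function(tr) tr$s,
                             numeric(nrow(reps[[1]]))))
    s_avg <- s_avg / max(s_avg)
    out[[i]] <- switching_trace(reps[[1]]$t, s_avg, reps[[1]]$phase_id,
                                schedule = schedule,
                                meta = list(ca = ca_list[i], n_rep = n_rep))
  }
  out
}

#' Synthetic tomography phantom stack
#'
#' Per pixel, the local fluence is `exp(-mu_eff * depth)` from the
#' illuminated side.  Sensor pixels follow the forward switching model with
#' rates scaled by the local fluence; blood pixels emit a constant signal;
#' background is zero.  The optoacoustic amplitude is proportional to
#' absorber strength times fluence.  Pulse samples are averaged over
#' `pulses_per_frame` and additive Gaussian noise is applied per frame.
#'
#' @param layout A [phantom_layout()].
#' @param sensor A [sensor_model()].
#' @param schedule An [illumination_schedule()].
#' @param noise_sd Additive per-frame noise standard deviation, a.u.
#' @param seed Integer seed (bit-reproducible).
#' @return An [image_time_series()] with `layout_truth` attached.
#' @export
make_phantom_stack <- function(layout, sensor, schedule, noise_sd = 0,
                               seed = NULL) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(sensor, "sensor_model"),
            inherits(schedule, "illumination_schedule"))
  h <- layout$height; w <- layout$width
  nf <- n_frames(schedule)
  masks <- lapply(layout$regions, function(r) region_mask(layout, r))
  # overlap check
  cover <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(cover > 1L)) stop("phantom regions overlap")
  flu <- fluence_map(layout)
  frames <- array(0, dim = c(nf, h, w))
  depth_axis <- if (layout$illum_side %in% c("top", "bottom")) "row" else "col"
  for (i in seq_along(layout$regions)) {
    r <- layout$regions[[i]]
    m <- masks[[i]]
    idx <- which(m)                       # column-major over [h, w]
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    if (r$kind == "blood") {
      for (k in seq_along(idx))
        frames[, rows[k], cols[k]] <- r$strength * flu[rows[k], cols[k]]
    } else {
      key <- if (depth_axis == "row") rows else cols
      for (u in unique(key)) {
        sel <- which(key == u)
        fl <- flu[rows[sel[1]], cols[sel[1]]]
        tr <- simulate_trace(sensor, schedule, r$ca, noise_sd = 0,
                             intensity_scale = fl)
        vals <- r$strength * fl * tr$s
        for (k in sel) frames[, rows[k], cols[k]] <- vals
      }
    }
  }
  if (noise_sd > 0) {
    add <- function() array(rnorm(length(frames), 0, noise_sd), dim(frames))
    frames <- frames + if (is.null(seed)) add() else
      withr::with_seed(seed, add())
  }
  image_time_series(frames, schedule, layout_truth = layout,
                    meta = list(noise_sd = noise_sd, seed = seed))
}

# Deterministic fan-out of a base seed into independent stage seeds
# (kept < 2^31 - 1).
stage_seed <- function(base, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 65521
  as.integer((as.numeric(base) + h * 7919) %% 2147483646) + 1L
}
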