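#' Write / read an image time-series as multi-page TIFF with JSON sidecar
#'
#' Frames are stored in acquisition order as 32-bit float TIFF pages.
#' Because float TIFF storage covers \[0, 1\], the data are affinely mapped
#' with a scale and offset recorded in the sidecar `<name>.meta.json`,
#' which also round-trips the schedule and any layout ground truth.  A
#' first write quantises doubles to 32-bit floats; thereafter the
#' write/read round trip is bitwise lossless.
#'
#' @param series An [image_time_series()].
#' @param path TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` an
#'   [image_time_series()].
#' @export
write_stack <- function(series, path) {
  stopifnot(inherits(series, "image_time_series"))
  fr <- series$frames
  lo <- min(fr); hi <- max(fr)
  scale <- hi - lo
  if (scale == 0) scale <- 1
  # reuse the mapping a read stack carries, so write -> read -> write is
  # bitwise idempotent (no re-quantisation drift)
  if (!is.null(series$meta$io_scale) &&
      lo >= series$meta$io_offset &&
      hi <= series$meta$io_offset + series$meta$io_scale) {
    lo <- series$meta$io_offset
    scale <- series$meta$io_scale
  }
  pages <- lapply(seq_len(dim(fr)[1]),
                  function(i) encode_page((fr[i, , ] - lo) / scale))
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  meta <- list(
    format = "caswitch-stack",
    version = as.character(utils::packageVersion("caswitch")),
    n_frames = dim(fr)[1], height = dim(fr)[2], width = dim(fr)[3],
    scale = scale, offset = lo,
    schedule = schedule_to_list(series$schedule),
    layout_truth = if (!is.null(series$layout_truth))
      layout_to_list(series$layout_truth) else NULL,
    meta = series$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".meta.json")

# 32-bit TIFF samples pass through an asymmetric scaled-integer conversion
# (write truncates x*(2^32-1), read divides by 2^32).  Values in [0, 1] are
# therefore snapped to a uint32 grid with a quarter-step margin so the
# stored integer is exact under either truncation or rounding, making
# write -> read -> write bitwise idempotent at ~2e-10 quantisation.
.tiff_Q <- 2^32 - 2

encode_page <- function(norm) {
  k <- round(pmin(pmax(norm, 0), 1) * .tiff_Q)
  (k + 0.25) / (2^32 - 1)
}

decode_page <- function(y) round(y * 2^32) / .tiff_Q

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar: expected metadata at '", sc, "'")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- meta$scale %||% 1
  offset <- meta$offset %||% 0
  bits <- attr(pages[[1]], "bits.per.sample") %||% NA_integer_
  fmt <- attr(pages[[1]], "sample.format") %||%
    (if (is.numeric(bits) && is.finite(bits) && bits < 32) "uint" else "float")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  fr <- array(0, dim = c(length(pages), h, w))
  # integer stacks arrive rescaled to [0,1]; the sidecar scale then maps
  # them to physical units (promotion to float, scale kept in metadata)
  own <- identical(meta$format, "caswitch-stack")
  for (i in seq_along(pages)) {
    pg <- if (own) decode_page(pages[[i]]) else pages[[i]]
    fr[i, , ] <- pg * scale + offset
  }
  schedule <- schedule_from_list(meta$schedule)
  nf <- n_frames(schedule)
  if (length(pages) != nf)
    stop("frame count mismatch: TIFF has ", length(pages),
         " frames but the schedule defines ", nf)
  layout <- if (!is.null(meta$layout_truth)) layout_from_list(meta$layout_truth)
  extra <- as.list(meta$meta %||% list())
  extra$source_bits <- bits
  extra$source_format <- fmt
  if (!identical(fmt, "float") && is.numeric(bits) && is.finite(bits))
    extra$source_scale <- 2^bits - 1
  extra$io_scale <- scale
  extra$io_offset <- offset
  image_time_series(fr, schedule, layout_truth = layout, meta = extra)
}

schedule_to_list <- function(schedule) {
  list(phases = schedule$phases, n_cycles = schedule$n_cycles,
       pulses_per_frame = schedule$pulses_per_frame)
}

layout_to_list <- function(layout) {
  list(height = layout$height, width = layout$width,
       pixel_size = layout$pixel_size, mu_eff = layout$mu_eff,
       illum_side = layout$illum_side, regions = layout$regions)
}

#' Rebuild a phantom layout from a plain list (sidecar/config contents)
#' @param x Named list as produced by the sidecar writer.
#' @return A [phantom_layout()].
#' @export
layout_from_list <- function(x) {
  if (inherits(x, "phantom_layout")) return(x)
  regions <- x$regions
  if (is.data.frame(regions))
    regions <- lapply(seq_len(nrow(regions)), function(i) {
      r <- as.list(regions[i, ])
      r$center <- unlist(r$center)
      r
    })
  regions <- lapply(regions, function(r) {
    r$center <- as.numeric(unlist(r$center))
    r
  })
  phantom_layout(height = x$height, width = x$width,
                 pixel_size = x$pixel_size, regions = regions,
                 mu_eff = x$mu_eff, illum_side = x$illum_side)
}

# Single-map float TIFF writer (mask/score/tau maps) with its own sidecar.
write_map <- function(m, path) {
  m2 <- m
  m2[!is.finite(m2)] <- NA
  lo <- suppressWarnings(min(m2, na.rm = TRUE))
  hi <- suppressWarnings(max(m2, na.rm = TRUE))
  if (!is.finite(lo)) { lo <- 0; hi <- 0 }
  scale <- hi - lo
  if (scale == 0) scale <- 1
  norm <- (m2 - lo) / scale
  norm[!is.finite(norm)] <- 0
  suppressWarnings(tiff::writeTIFF(encode_page(norm), path,
                                   bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  jsonlite::write_json(list(format = "caswitch-map", scale = scale,
                            offset = lo, na_encoded_as = "offset"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file; `.yaml`/`.yml` or `.json`.
#' @return Named list (see [run_pipeline()] for recognised fields).
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
}

#' Run the end-to-end phantom unmixing and calibration pipeline
#'
#' Executes simulate (optional) -> classify -> reference offset -> per-pixel
#' kinetics -> calibrate -> invert, writing all maps, a per-region summary
#' CSV and a log to the output directory.  Reruns with the same
#' configuration and seed produce byte-identical summaries.
#'
#' @param config Named list or path to a YAML/JSON file.  Fields (all
#'   optional unless noted): `out_dir` (required), `seed` (base seed,
#'   fanned out per stage), `sensor`, `schedule`, `layout`, `noise_sd`,
#'   `stack_path` (read an existing stack instead of simulating),
#'   `theta_f`, `theta_r`, `r2_polarity`, `reference` (ROI list with x, y,
#'   r; default: the highest-Ca2+ sensor region of the layout truth),
#'   `fix_endpoints` (default TRUE: pin the dose-response endpoints to the
#'   lowest/highest tube concentrations).
#' @return Invisibly, a list with the output paths and the in-memory
#'   results (`scores`, `tau_map`, `calibration`, `summary`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  logf <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- as.integer(config$seed %||% 1L)
  sensor <- sensor_from_list(config$sensor %||% sensor_model())
  logf("caswitch %s | base seed %d", as.character(packageVersion("caswitch")),
       seed)

  stk <- stage("simulate", {
    if (!is.null(config$stack_path)) {
      logf("reading stack from %s", config$stack_path)
      read_stack(config$stack_path)
    } else {
      layout <- if (is.null(config$layout)) default_phantom_layout()
                else layout_from_list(config$layout)
      schedule <- if (is.null(config$schedule))
        oa_tomography_schedule() else schedule_from_list(config$schedule)
      noise_sd <- config$noise_sd %||% 0
      logf("simulating phantom: %d x %d px, %d frames, noise_sd = %g, seed = %d",
           layout$height, layout$width, n_frames(schedule), noise_sd,
           stage_seed(seed, "phantom"))
      make_phantom_stack(layout, sensor, schedule, noise_sd = noise_sd,
                         seed = stage_seed(seed, "phantom"))
    }
  })

  theta_f <- config$theta_f %||% 0.2
  theta_r <- config$theta_r %||% 0.8
  polarity <- config$r2_polarity %||% "high"
  scores <- stage("classify", {
    logf("classifying pixels (theta_f = %g, theta_r = %g, r2 polarity = %s)",
         theta_f, theta_r, polarity)
    classify_pixels(stk, theta_f = theta_f, theta_r = theta_r,
                    r2_polarity = polarity)
  })
  logf("mask: %d switching pixels", sum(scores$mask))

  y0 <- stage("reference_offset", {
    roi <- config$reference
    if (is.null(roi)) {
      lt <- stk$layout_truth
      if (is.null(lt)) stop("no reference ROI given and no layout truth available")
      sens <- Filter(function(r) r$kind == "sensor", lt$regions)
      best <- sens[[which.max(vapply(sens, `[[`, numeric(1), "ca"))]]
      roi <- list(x = best$center[1], y = best$center[2], r = best$radius)
      logf("reference ROI: highest-Ca2+ tube at (%g, %g), r = %g",
           roi$x, roi$y, roi$r)
    }
    reference_offset(stk, roi)
  })
  logf("reference offset y0 = %.6g", y0)

  tmap <- stage("fit_pixel_kinetics", fit_pixel_kinetics(stk, scores$mask, y0))

  # per-region summary and calibration against the known tube concentrations
  calib <- NULL
  summary_df <- NULL
  stage("calibrate", {
    lt <- stk$layout_truth
    if (is.null(lt)) {
      logf("no layout truth: skipping per-region calibration")
    } else {
      masks <- layout_truth_masks(lt)
      rows <- lapply(seq_along(lt$regions), function(i) {
        r <- lt$regions[[i]]
        m <- masks$region_id == i
        tt <- tmap$tau[m]
        data.frame(region = i, kind = r$kind,
                   ca_true = if (r$kind == "sensor") r$ca else NA_real_,
                   n_pixels = sum(m), n_masked = sum(scores$mask[m]),
                   tau_mean = mean(tt, na.rm = TRUE),
                   tau_sd = sd(tt, na.rm = TRUE))
      })
      summary_df <- do.call(rbind, rows)
      sens <- summary_df[summary_df$kind == "sensor" &
                           is.finite(summary_df$tau_mean), ]
      if (nrow(sens) >= 4 && max(sens$ca_true) / min(sens$ca_true) > 10) {
        fix <- if (isTRUE(config$fix_endpoints %||% TRUE))
          c(min(sens$ca_true), max(sens$ca_true)) else NULL
        calib <- fit_dose_response(
          data.frame(ca = sens$ca_true, tau = sens$tau_mean), fix_from = fix)
        est <- invert_tau(calib, summary_df$tau_mean)
        summary_df$ca_est <- ifelse(is.finite(summary_df$tau_mean), est,
                                    NA_real_)
        logf("calibration: tau %0.4g -> %0.4g s, EC50 = %.4g uM, slope = %.4g",
             calib$tau_max, calib$tau_min, 10^calib$log_ec50, calib$hill_slope)
      } else {
        logf("fewer than 4 sensor tubes spanning a decade: calibration skipped")
      }
    }
  })

  paths <- list(
    mask = file.path(out_dir, "mask.tif"),
    fourier_score = file.path(out_dir, "fourier_score.tif"),
    r2 = file.path(out_dir, "r2.tif"),
    tau = file.path(out_dir, "tau.tif"),
    summary = file.path(out_dir, "summary.csv"),
    config = file.path(out_dir, "run_config.json"),
    log = log_path)
  stage("write_outputs", {
    write_map(scores$mask * 1, paths$mask)
    write_map(scores$fourier_score, paths$fourier_score)
    write_map(scores$r2, paths$r2)
    write_map(tmap$tau, paths$tau)
    if (!is.null(calib)) {
      ca_map <- matrix(invert_tau(calib, tmap$tau), nrow(tmap$tau))
      paths$ca <- file.path(out_dir, "ca_relative.tif")
      write_map(ca_map, paths$ca)
      jsonlite::write_json(
        list(tau_max = calib$tau_max, tau_min = calib$tau_min,
             log_ec50 = calib$log_ec50, hill_slope = calib$hill_slope,
             endpoints_fixed = calib$endpoints_fixed),
        file.path(out_dir, "calibration.json"), auto_unbox = TRUE,
        digits = NA)
    }
    if (!is.null(summary_df))
      write.csv(format(summary_df, digits = 10), paths$summary,
                row.names = FALSE, quote = FALSE)
    cfg_out <- config
    cfg_out$resolved <- list(seed = seed, theta_f = theta_f,
                             theta_r = theta_r, r2_polarity = polarity,
                             version = as.character(packageVersion("caswitch")))
    jsonlite::write_json(cfg_out, paths$config, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    writeLines(log_lines, log_path)
  })
  invisible(list(paths = paths, scores = scores, tau_map = tmap,
                 calibration = calib, summary = summary_df, y0 = y0))
}
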