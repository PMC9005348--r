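#!/usr/bin/env Rscript
# Tomography phantom unmixing end to end: simulate the four-concentration
# tube phantom, classify switching pixels, map decay constants, calibrate
# and invert to a relative Ca2+ map.
#
# Run from the repository root:  Rscript analysis/03_phantom_unmixing.R

suppressPackageStartupMessages(library(caswitch))
dir.create("results", showWarnings = FALSE)

cfg <- list(
  out_dir = "results/phantom_run",
  seed = 3L,
  sensor = list(kd = 0.46),
  layout = caswitch:::layout_to_list(default_phantom_layout()),
  # ten cycles of 120 + 120 pulses; frames averaged over ten pulses keep
  # the stack at 240 frames
  schedule = caswitch:::schedule_to_list(
    oa_tomography_schedule(pulses_per_frame = 10L)),
  noise_sd = 0.002)

res <- run_pipeline(cfg)

sens <- res$summary[res$summary$kind == "sensor", ]
message("Per-tube decay constants and recovered relative Ca2+:")
print(sens[, c("ca_true", "n_masked", "tau_mean", "tau_sd", "ca_est")],
      digits = 3)
ok <- identical(order(sens$ca_est), order(sens$ca_true))
message(sprintf("Recovered concentration ranking matches ground truth: %s",
                ok))
message("Maps and summary written to results/phantom_run/")
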