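#!/usr/bin/env Rscript
# One-command rerun of the whole analysis through the pipeline runner,
# plus a human-readable markdown report with stage provenance. Uses the
# same master seed as the step-by-step scripts.

library(skerrydiv)

seed <- 20260928
cfg <- pipeline_config(
  landscape = landscape_params(nx = 10, ny = 40, n_islands = 240, seed = seed),
  simulation = simulation_params(seed = seed + 1),
  rc_reps = 999, mantel_perms = 9999, seed = seed)

bundle <- run_pipeline(cfg)
write_pipeline(bundle, file.path("results", "pipeline"))
writeLines(summarise_pipeline(bundle), file.path("results", "report.md"))
cat("report written to results/report.md\n")
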