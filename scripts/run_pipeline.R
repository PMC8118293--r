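#!/usr/bin/env Rscript
# Thin command-line wrapper over beescape::run_pipeline(): runs the full
# synthetic analysis (simulate -> buffers -> rates -> threats -> quality
# -> indices) and writes CSV/ASC/GeoJSON outputs plus a manifest.
#
# Usage: Rscript scripts/run_pipeline.R [--seed <int>] [--out <dir>]
#        [--rows <n>] [--cols <n>] [--sites <n>] [--conversion <rate>]

suppressPackageStartupMessages(library(beescape))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

cfg <- pipeline_config(sim = simulation_config(
  seed = as.integer(get_arg("--seed", "1")),
  grid_rows = as.integer(get_arg("--rows", "200")),
  grid_cols = as.integer(get_arg("--cols", "200")),
  n_sites = as.integer(get_arg("--sites", "10")),
  conversion_rate = as.numeric(get_arg("--conversion", "0.04"))
))
out_dir <- get_arg("--out", "pipeline_out")

res <- run_pipeline(cfg, out_dir = out_dir)
print(res$summary)
cat(sprintf("outputs written to %s\n", out_dir))
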