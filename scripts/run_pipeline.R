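#!/usr/bin/env Rscript
# Thin command-line wrapper over commfba::run_pipeline().
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] [--out DIR] [--seed N]
# Exit codes: 0 success, 2 validation error, 3 stage failure.

suppressPackageStartupMessages(library(commfba))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

cfg <- tryCatch({
  path <- get_opt("--config")
  cfg <- if (is.null(path)) scaled_config() else read_config(path)
  seed <- get_opt("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}, error = function(e) {
  message("configuration error: ", conditionMessage(e))
  quit(status = 2)
})

out <- get_opt("--out", "pipeline_output")
res <- tryCatch(
  run_pipeline(cfg, out_dir = out),
  error = function(e) {
    message("pipeline failure: ", conditionMessage(e))
    quit(status = 3)
  })
message("pipeline complete; outputs in ", normalizePath(out))
if (!is.null(res$endpoints)) {
  print(utils::head(res$endpoints[, c("metabolite", "p_wilcoxon",
                                      "p_adj_wilcoxon", "direction")]))
}
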