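#!/usr/bin/env Rscript
# Thin command-line wrapper over the priorselect package.
#
#   Rscript scripts/priorselect simulate --config cfg.yaml --out DIR [--seed N] [--overwrite]
#   Rscript scripts/priorselect run-all  --config cfg.yaml [--out DIR]
#   Rscript scripts/priorselect validate --config cfg.yaml

suppressPackageStartupMessages({
  library(optparse)
  library(priorselect)
})

`%||%` <- function(x, y) if (is.null(x)) y else x

args <- commandArgs(trailingOnly = TRUE)
if (!length(args) || !args[1] %in% c("simulate", "run-all", "validate")) {
  stop("usage: priorselect {simulate|run-all|validate} --config FILE [options]")
}
verb <- args[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--out", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--overwrite", action = "store_true", default = FALSE)
)), args = args[-1])

config <- yaml::read_yaml(opts$config)
if (!is.null(opts$seed)) config$seed <- opts$seed

if (verb == "validate") {
  chk <- validate_config(config)
  for (w in chk$warnings) message("warning: ", w)
  if (length(chk$errors)) {
    message("errors:\n  - ", paste(chk$errors, collapse = "\n  - "))
    quit(status = 1)
  }
  message("config OK")
} else if (verb == "simulate") {
  cfg <- do.call(synthetic_config,
                 c(config$synthetic %||% config,
                   if (!is.null(config$seed)) list(seed = config$seed)))
  bundle <- generate_dataset(cfg)
  write_dataset(bundle, opts$out %||% stop("simulate needs --out"),
                overwrite = opts$overwrite)
  message("wrote dataset to ", opts$out)
} else {
  res <- run_all(config, out_dir = opts$out)
  message(sprintf("done: %d drugs x strategy records, %d drug(s) excluded",
                  nrow(res$aggregated), length(res$excluded)))
}
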