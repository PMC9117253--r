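#!/usr/bin/env Rscript
# Thin command-line wrapper over ubidyn::run_pipeline(): reads a YAML run
# configuration and writes the run directory.
#
# Usage: Rscript scripts/run_pipeline.R --config run.yaml --out run_dir
#        Rscript scripts/run_pipeline.R --preset dia --out run_dir [--seed N]

suppressMessages({
  library(optparse)
  library(ubidyn)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration"),
  make_option("--preset", type = "character", default = "dia",
              help = "preset when no config file is given [dda|dia|his10]"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "ubidyn_run")
)))

cfg <- tryCatch({
  if (!is.null(opts$config)) {
    read_run_config(opts$config)
  } else {
    run_config(opts$preset, seed = opts$seed)
  }
}, error = function(e) {
  message("configuration error: ", conditionMessage(e))
  quit(status = 2)
})

res <- tryCatch(run_pipeline(cfg, opts$out), error = function(e) {
  message("pipeline error: ", conditionMessage(e))
  quit(status = 1)
})
cat(res$log, sep = "\n")
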