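#!/usr/bin/env Rscript

# Thin command-line wrapper over faersignal::run_pipeline().
# Usage:
#   Rscript scripts/faersignal_pipeline.R --config config.yaml --outdir out
#   Rscript scripts/faersignal_pipeline.R --outdir out --seed 7   # synthetic demo

suppressPackageStartupMessages({
  library(optparse)
  library(faersignal)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline config; omit for a synthetic demo run"),
  make_option("--outdir", type = "character", default = "faersignal_out"),
  make_option("--seed", type = "integer", default = 1L))))

config <- if (is.null(opts$config)) {
  list(synthetic = list(), seed = opts$seed)
} else {
  opts$config
}
manifest <- run_pipeline(config, opts$outdir)
message("pipeline complete; outputs in ", opts$outdir)
invisible(manifest)
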