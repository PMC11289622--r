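#!/usr/bin/env Rscript
# Thin wrapper: run the end-to-end pipeline from a JSON configuration.
#
# Usage: Rscript scripts/run_pipeline.R --config <config.json> --out <dir>
#        Rscript scripts/run_pipeline.R --seed 1 --out <dir>   (defaults)

suppressMessages({
  library(optparse)
  library(peritract)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "pipeline_out")
)))

config <- if (is.null(opts$config)) {
  pipeline_config(seed = opts$seed)
} else {
  read_pipeline_config(opts$config)
}
res <- run_pipeline(config, opts$out)
message("pipeline outputs written to ", opts$out)
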