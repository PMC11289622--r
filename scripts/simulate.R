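#!/usr/bin/env Rscript
# Thin wrapper over the synthetic-data module.
#
# Usage: Rscript scripts/simulate.R --what spots|ephys --seed <int> --out <path>
#   spots: writes a 10x-convention spot dataset directory
#   ephys: writes a flat float32 recording + JSON sidecar

suppressMessages({
  library(optparse)
  library(peritract)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--what", type = "character", default = "spots"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "simulated")
)))

if (opts$what == "spots") {
  ds <- simulate_spot_dataset(sim_config(seed = opts$seed))
  write_spot_dataset(ds, opts$out)
  message("spot dataset written to ", opts$out)
} else if (opts$what == "ephys") {
  rec <- simulate_recording(ephys_sim_config(seed = opts$seed))
  dir.create(dirname(opts$out), recursive = TRUE, showWarnings = FALSE)
  path <- if (grepl("\\.bin$", opts$out)) opts$out else
    file.path(opts$out, "recording.bin")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_recording(rec, path)
  message("recording written to ", path)
} else {
  stop("--what must be 'spots' or 'ephys'")
}
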