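#!/usr/bin/env Rscript
# Thin command-line wrapper over ssgwaspath::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --out <dir> [--config <yaml>] [--seed <int>]
#
# With --config, the YAML is read via read_config() (and --seed, if given,
# overrides the seed it contains); otherwise the default desk-scale
# synthetic configuration is used.

suppressPackageStartupMessages({
  library(optparse)
  library(ssgwaspath)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "pipeline_out")
)))

cfg <- if (is.null(opts$config)) pipeline_config() else read_config(opts$config)
if (!is.null(opts$seed)) {
  vals <- unclass(cfg)
  vals$seed <- opts$seed
  cfg <- do.call(pipeline_config, vals)
}

res <- run_pipeline(cfg, out_dir = opts$out)
print(res$summary, width = Inf)
cat("outputs written to", opts$out, "\n")
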