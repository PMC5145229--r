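#!/usr/bin/env Rscript
# Thin shell entry point over the package's pipeline functions.
#
#   Rscript scripts/run_pipeline.R generate --out <dir> [--config cfg.yaml] [--seed N]
#   Rscript scripts/run_pipeline.R evaluate --out <dir> [--dataset <dir>]
#                                  [--config cfg.yaml] [--seed N] [--exclude hop]
#   Rscript scripts/run_pipeline.R compare <runA> <runB>

suppressPackageStartupMessages({
  library(optparse)
  library(fallfusion)
})

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) stop("usage: run_pipeline.R generate|evaluate|compare ...")
cmd <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--out", type = "character", default = "run"),
  make_option("--config", type = "character", default = NULL),
  make_option("--dataset", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--exclude", type = "character", default = NULL,
              help = "comma-separated ADL subtypes to exclude"),
  make_option("--roc", action = "store_true", default = FALSE)))

if (cmd == "generate") {
  o <- parse_args(parser, args[-1])
  gen <- if (!is.null(o$config)) {
    a <- yaml::read_yaml(o$config)$generator
    a$seed <- o$seed
    do.call(generatorConfig, a)
  } else generatorConfig(seed = o$seed)
  writeDataset(genDataset(gen), o$out)
  message("wrote trace files to ", o$out)
} else if (cmd == "evaluate") {
  o <- parse_args(parser, args[-1])
  excl <- if (!is.null(o$exclude)) strsplit(o$exclude, ",")[[1]] else NULL
  runEvaluation(o$out, dataset = o$dataset, configFile = o$config,
                excludedSubtypes = excl, seed = o$seed, writeRoc = o$roc)
} else if (cmd == "compare") {
  dirs <- args[-1][!startsWith(args[-1], "--")]
  if (length(dirs) != 2) stop("compare needs two run directories")
  cmp <- compareRuns(dirs[1], dirs[2])
  print(cmp$signSummary)
  invisible(write.csv(cmp$deltas, file.path(dirs[2], "deltas.csv"),
                      row.names = FALSE))
} else stop("unknown subcommand: ", cmd)
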