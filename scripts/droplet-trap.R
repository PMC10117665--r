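#!/usr/bin/env Rscript
# Thin command-line wrapper over the dropletTrap pipeline functions.
#
#   Rscript scripts/droplet-trap.R simulate [--config cfg.yaml] [--seed N] --out DIR
#   Rscript scripts/droplet-trap.R track STACK.tif [--config cfg.yaml] --out DIR
#   Rscript scripts/droplet-trap.R analyze TRAJ_DIR [--config cfg.yaml] --out DIR
#   Rscript scripts/droplet-trap.R demo [--seed N] --out DIR

suppressMessages({
  library(optparse)
  library(dropletTrap)
})

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  message("usage: droplet-trap.R <simulate|track|analyze|demo> [options]")
  quit(status = 1)
}
cmd <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "droplet-trap-out"),
  make_option("--verbose", action = "store_true", default = FALSE)
))
parsed <- parse_args(parser, args = args[-1], positional_arguments = TRUE)
opt <- parsed$options
pos <- parsed$args

log_ <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

cfg <- tryCatch({
  base <- if (is.null(opt$config)) list() else yaml::read_yaml(opt$config)
  if (!is.null(opt$seed)) base$seed <- opt$seed
  if (opt$verbose) base$verbose <- TRUE
  validateRunConfig(base)
}, error = function(e) {
  message("config error: ", conditionMessage(e))
  quit(status = 1)
})
log_("resolved seed: ", cfg$seed)

status <- tryCatch({
  switch(cmd,
    simulate = {
      res <- runCohortSimulation(cfg, opt$out)
      log_("wrote ", length(res$files), " trajectories to ", opt$out)
      0L
    },
    track = {
      if (!length(pos)) stop("track needs a TIFF stack path")
      res <- runSceneTracking(pos[1], cfg, opt$out)
      log_("pattern: ", res$classification$label)
      0L
    },
    analyze = {
      if (!length(pos)) stop("analyze needs a trajectory directory")
      res <- runMobilityAnalysis(pos[1], cfg, opt$out)
      log_("classes: ", paste(res$table$class, collapse = ", "))
      0L
    },
    demo = {
      simDir <- file.path(opt$out, "cohort")
      runCohortSimulation(cfg, simDir)
      res <- runMobilityAnalysis(simDir, cfg, file.path(opt$out, "analysis"))
      print(res$table)
      log_("demo outputs in ", opt$out)
      0L
    },
    {
      message("unknown command: ", cmd)
      1L
    })
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
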