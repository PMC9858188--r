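#!/usr/bin/env Rscript
# Thin command-line wrapper over the her2quant package.
#
#   Rscript scripts/her2quant.R simulate --class 3+ --tiles 4 --seed 1 --out DIR
#   Rscript scripts/her2quant.R train    --n 200 --seed 1 --out model_info.json
#   Rscript scripts/her2quant.R score    --slide slide.tiff [--config cfg.yaml] --out DIR
#   Rscript scripts/her2quant.R eval     --pred pred.csv --truth truth.csv --out DIR

suppressMessages({
  library(her2quant)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: her2quant.R <simulate|train|score|eval> [options]", call. = FALSE)
}
cmd <- args[[1]]
rest <- args[-1]

run <- switch(cmd,
  simulate = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--class", type = "character", default = "3+", dest = "cls"),
      make_option("--tiles", type = "integer", default = 4L),
      make_option("--seed", type = "integer", default = 1L),
      make_option("--out", type = "character", default = "slide_out")
    )), args = rest)
    sl <- make_slide(o$cls, n_tiles = o$tiles, rng_seed = o$seed)
    write_synthetic_slide(sl, o$out)
    cat("wrote synthetic", o$cls, "slide to", o$out, "\n")
  },
  train = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--n", type = "integer", default = 200L),
      make_option("--seed", type = "integer", default = 1L),
      make_option("--out", type = "character", default = "model_info.json")
    )), args = rest)
    set_ <- make_patch_set(o$n %/% 2, o$n %/% 2, rng_seed = o$seed)
    clf <- train_classifier(set_, config = train_config(seed = o$seed))
    jsonlite::write_json(as.list(glance(clf)), o$out, auto_unbox = TRUE,
                         digits = NA)
    cat(sprintf("validation accuracy %.3f; wrote %s\n",
                clf$validation_accuracy, o$out))
  },
  score = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--slide", type = "character"),
      make_option("--config", type = "character", default = NULL),
      make_option("--seed", type = "integer", default = 1L),
      make_option("--out", type = "character", default = "report_out")
    )), args = rest)
    cfg <- if (is.null(o$config)) her2_config(seed = o$seed)
           else read_config(o$config)
    rep <- run_slide(o$slide, cfg, out_dir = o$out)
    cat(sprintf("IHC class %s (%s); artifacts in %s\n",
                rep$ihc_class, rep$her2_status, o$out))
  },
  eval = function() {
    o <- parse_args(OptionParser(option_list = list(
      make_option("--pred", type = "character"),
      make_option("--truth", type = "character"),
      make_option("--out", type = "character", default = "eval_out")
    )), args = rest)
    out <- run_eval(o$pred, o$truth)
    dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
    for (m in names(out)) {
      write_confusion_csv(out[[m]], file.path(o$out, paste0(m, "_confusion.csv")))
      cat(sprintf("%s accuracy: %.3f\n", m, out[[m]]$accuracy))
    }
  },
  stop("unknown command: ", cmd, call. = FALSE)
)
invisible(run())
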