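#!/usr/bin/env Rscript
# Optional reproduction of the external-data analyses. These require
# datasets that are not shipped with the package:
#   * the machina simulated collection (75 datasets after excluding the
#     five containing a tumor sample with a single variant), from
#     https://github.com/raphael-group/machina
#   * the 40 metastatic-cancer exome datasets of Zhai et al.
# Point --counts-dir at a directory of read-count tables in the canonical
# interleaved TSV dialect (one file per patient/dataset, named
# <dataset>.tsv), with optional <dataset>.truth_genotypes.tsv /
# <dataset>.truth_paths.tsv files for scoring. Expect multi-hour runtimes
# on the full collections.
#
# Usage:
#   Rscript scripts/reproduce_external.R --counts-dir DIR --primary P \
#       [--replicates 30] [--seed 1] [--out-dir results/external]

suppressPackageStartupMessages(library(cloneboot))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
counts_dir <- get_arg("--counts-dir", NULL)
primary <- get_arg("--primary", NULL)
n_rep <- as.integer(get_arg("--replicates", "30"))
seed <- as.integer(get_arg("--seed", "1"))
out_dir <- get_arg("--out-dir", "results/external")
if (is.null(counts_dir) || !dir.exists(counts_dir))
  stop("--counts-dir must name an existing directory of count TSVs")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(counts_dir, pattern = "\\.tsv$", full.names = TRUE)
files <- files[!grepl("\\.truth_", files)]
# exclusion rule: drop datasets where any sample carries a single variant
usable <- character()
for (f in files) {
  rc <- tryCatch(read_counts(f), error = function(e) NULL)
  if (is.null(rc)) next
  if (any(rowSums(rc$alt > 0) <= 1L)) next
  usable <- c(usable, f)
}
cat(length(usable), "dataset(s) after the exclusion filter\n")

clone_rows <- list(); path_rows <- list()
for (f in usable) {
  ds <- sub("\\.tsv$", "", basename(f))
  rc <- read_counts(f)
  fit <- suppressWarnings(
    cloneboot(rc, primary = primary,
              config = cb_config(n_replicates = n_rep, rng_seed = seed),
              keep_replicates = FALSE))
  sup <- fit$consensus$support
  row <- data.frame(dataset = ds, support = sup)
  tg <- file.path(counts_dir, paste0(ds, ".truth_genotypes.tsv"))
  if (file.exists(tg)) {
    truth <- read_genotypes(tg)
    row$ge <- unname(genotype_error(fit$consensus$genotypes, truth)$per_clone)
  }
  clone_rows[[ds]] <- row
  if (!is.null(fit$replicate_histories)) {
    ps <- path_supports(fit$replicate_histories)
    tp <- file.path(counts_dir, paste0(ds, ".truth_paths.tsv"))
    if (file.exists(tp)) {
      th <- read_history(tp)
      ps$is_tp <- paste(ps$source, ps$destination) %in%
        paste(th$source, th$destination)
    }
    ps$dataset <- ds
    path_rows[[ds]] <- ps
  }
  write_outputs(fit$consensus$genotypes, fit$point$frequencies,
                fit$point$tree, fit$consensus_migration,
                file.path(out_dir, ds))
}

clones <- do.call(rbind, clone_rows)
utils::write.table(clones, file.path(out_dir, "consensus_clone_support.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("clones with <=10%% support: %.1f%%\n",
            100 * mean(clones$support <= 10)))
if (length(path_rows)) {
  paths <- do.call(rbind, path_rows)
  utils::write.table(paths, file.path(out_dir, "path_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(paths$is_tp)) {
    cat(sprintf("TP path support median: %.1f%%; FP: %.1f%%\n",
                stats::median(paths$support_percent[paths$is_tp]),
                stats::median(paths$support_percent[!paths$is_tp])))
  }
}
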