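#' Bootstrap-support of every pooled migration path
#'
#' Support of each distinct (source, destination) path over a list of
#' per-replicate histories, without any reachability filtering.
#'
#' @param histories List of `"migration_history"` objects or path data
#'   frames.
#' @return Data frame `source`, `destination`, `support_percent`.
#' @export
path_supports <- function(histories) {
  n_rep <- length(histories)
  dfs <- lapply(histories, function(h)
    if (inherits(h, "migration_history")) h$paths else h)
  keys_by_rep <- lapply(dfs, function(d)
    unique(paste(d$source, d$destination, sep = "\r")))
  all_keys <- sort(unique(unlist(keys_by_rep)))
  support <- vapply(all_keys, function(k)
    100 * sum(vapply(keys_by_rep, function(x) k %in% x, TRUE)) / n_rep,
    numeric(1))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  data.frame(source = vapply(parts, `[[`, "", 1),
             destination = vapply(parts, `[[`, "", 2),
             support_percent = unname(support))
}

#' Simulation benchmark of the bootstrap approach
#'
#' Generates a collection of simulated metastatic-tumor datasets (5 tumor
#' samples; 8-12 clones; 30-60 SNVs; negative-binomial depth with mean 100;
#' monoclonal or, where clone numbers permit, polyclonal seeding), runs the
#' full bootstrap clone-inference pipeline on each, and scores consensus
#' clones and migration paths against the simulated truth: per consensus
#' clone its bootstrap support and genotype error (distance to the nearest
#' true clone over sequence length, ambiguous states costing one half), and
#' per pooled migration path its bootstrap support and true/false-positive
#' status.
#'
#' @param n_datasets Number of simulated datasets.
#' @param seed Master seed; all per-dataset seeds derive from it.
#' @param n_replicates Bootstrap replicates per dataset.
#' @param depth_mean Mean sequencing depth.
#' @return A list of class `"cb_benchmark"`: `clones` (data frame `dataset`,
#'   `support`, `ge`), `paths` (data frame `dataset`, `source`,
#'   `destination`, `support_percent`, `is_tp`), `datasets` (per-dataset
#'   parameter table).
#' @export
run_benchmark <- function(n_datasets = 10L, seed = 1L, n_replicates = 30L,
                          depth_mean = 100) {
  sub_seeds <- derive_seeds(seed, 3L * n_datasets)
  clone_rows <- list(); path_rows <- list(); ds_rows <- list()
  for (i in seq_len(n_datasets)) {
    n_clones <- 8L + (i - 1L) %% 5L
    n_snvs <- 30L + ((i - 1L) * 7L) %% 31L
    seeding <- if (i %% 2L == 0L && n_clones >= 9L) "polyclonal" else
      "monoclonal"
    truth <- simulate_truth(n_clones, n_snvs, 5L, seeding = seeding,
                            seed = sub_seeds[3L * i - 2L])
    rc <- simulate_reads(truth, depth_mean = depth_mean,
                         seed = sub_seeds[3L * i - 1L])
    fit <- suppressWarnings(
      cloneboot(rc, primary = "P",
                config = cb_config(n_replicates = n_replicates,
                                   rng_seed = sub_seeds[3L * i]),
                keep_replicates = FALSE))
    ge <- genotype_error(fit$consensus$genotypes, truth$genotypes)$per_clone
    clone_rows[[i]] <- data.frame(dataset = i,
                                  support = fit$consensus$support,
                                  ge = unname(ge))
    ps <- path_supports(fit$replicate_histories)
    true_keys <- paste(truth$history$source, truth$history$destination)
    ps$is_tp <- paste(ps$source, ps$destination) %in% true_keys
    ps$dataset <- i
    path_rows[[i]] <- ps
    ds_rows[[i]] <- data.frame(dataset = i, n_clones = n_clones,
                               n_snvs = n_snvs, seeding = seeding)
  }
  structure(list(clones = do.call(rbind, clone_rows),
                 paths = do.call(rbind, path_rows),
                 datasets = do.call(rbind, ds_rows)),
            class = "cb_benchmark")
}

#' @export
print.cb_benchmark <- function(x, ...) {
  cl <- x$clones
  hi <- cl$support > 50
  cat(sprintf("Simulation benchmark: %d dataset(s), %d consensus clone(s)\n",
              nrow(x$datasets), nrow(cl)))
  cat(sprintf("  median GE of clones with >50%% support: %.4f (n = %d)\n",
              stats::median(cl$ge[hi]), sum(hi)))
  cat(sprintf("  clones with <=10%% support: %.1f%%\n",
              100 * mean(cl$support <= 10)))
  p <- x$paths
  cat(sprintf("  path support medians: TP %.1f%% (n = %d), FP %.1f%% (n = %d)\n",
              stats::median(p$support_percent[p$is_tp]), sum(p$is_tp),
              stats::median(p$support_percent[!p$is_tp]), sum(!p$is_tp)))
  invisible(x)
}
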