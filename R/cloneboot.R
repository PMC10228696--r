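#' Clone inference with bootstrap confidence
#'
#' The main entry point. Runs the clone-deconvolution engine on the
#' observed read counts (the point estimate), generates bootstrap replicate
#' datasets by per-position read resampling, re-infers clones in every
#' replicate, groups near-identical bootstrap clones into consensus clones
#' with bootstrap support, and — when a primary tumor site is named —
#' infers a migration history per replicate and aggregates them into a
#' consensus migration history with per-path support.
#'
#' @param counts A `read_counts` object (see [read_counts()] /
#'   [read_count_table()]).
#' @param primary Primary tumor site id (a sample id), or NULL to skip
#'   migration inference. Samples are taken to be one tumor site each.
#' @param driver_labels Optional named logical vector flagging driver SNVs;
#'   consumed by the per-path driver annotation.
#' @param config A [cb_config()]; `config$rng_seed` seeds the bootstrap.
#' @param keep_replicates Keep per-replicate predictions in the result
#'   (default TRUE; set FALSE to save memory on large runs).
#' @return An object of class `"cloneboot"` with components:
#'   \describe{
#'     \item{point}{the point-estimate `clone_prediction`}
#'     \item{consensus}{consensus clone genotypes (NA = ambiguous) and
#'       `support` (percent per consensus clone)}
#'     \item{replicate_predictions}{per-replicate `clone_prediction`s}
#'     \item{point_history, consensus_migration, replicate_histories,
#'       driver_comparison}{migration results when `primary` is given}
#'     \item{manifest}{configuration snapshot and per-replicate seeds}
#'   }
#' @export
#' @examples
#' truth <- simulate_truth(n_clones = 4, n_snvs = 16, n_samples = 3, seed = 3)
#' rc <- simulate_reads(truth, depth_mean = 300, seed = 4)
#' fit <- cloneboot(rc, primary = "P", config = cb_config(n_replicates = 5))
#' fit
cloneboot <- function(counts, primary = NULL, driver_labels = NULL,
                      config = cb_config(), keep_replicates = TRUE) {
  stopifnot(inherits(counts, "read_counts"))
  point <- run_clonefinder_plus(counts, config)

  reps <- make_replicate_set(counts, n = config$n_replicates,
                             seed = config$rng_seed)
  rep_preds <- lapply(reps$replicates, function(r)
    tryCatch(suppressWarnings(run_clonefinder_plus(r, config)),
             error = function(e) NULL))
  ok <- !vapply(rep_preds, is.null, TRUE)
  if (!all(ok))
    warning(sum(!ok), " bootstrap replicate(s) failed clone inference ",
            "and were excluded")
  rep_preds <- rep_preds[ok]
  if (length(rep_preds) == 0L) stop("clone inference failed in every replicate")

  clone_sets <- lapply(rep_preds, function(p) p$genotypes)
  cons <- consensus_clones(clone_sets, cutoff = config$group_cutoff,
                           base_threshold = config$base_threshold)

  out <- list(point = point, consensus = cons,
              counts = counts,
              manifest = list(config = config, seeds = reps$seeds,
                              n_replicates_ok = length(rep_preds),
                              package_version =
                                as.character(utils::packageVersion("cloneboot"))))
  if (keep_replicates) out$replicate_predictions <- rep_preds

  if (!is.null(primary)) {
    if (!primary %in% counts$sample_ids)
      stop("primary site '", primary, "' is not a sample id")
    hist_one <- function(p) {
      occ <- occupancy_from_frequencies(p$frequencies, config$report_freq)
      infer_history(p$tree, occ, primary)
    }
    out$point_history <- hist_one(point)
    out$replicate_histories <- lapply(rep_preds, hist_one)
    out$consensus_migration <- consensus_history(
      out$replicate_histories, primary,
      threshold = config$support_threshold_paths)
    out$path_annotations <- lapply(seq_along(rep_preds), function(i)
      map_mutations_to_paths(rep_preds[[i]]$tree, rep_preds[[i]]$genotypes,
                             out$replicate_histories[[i]], driver_labels))
    out$driver_comparison <-
      suppressWarnings(compare_driver_rates(out$path_annotations, primary))
    out$primary <- primary
  }
  class(out) <- "cloneboot"
  out
}

#' @export
print.cloneboot <- function(x, ...) {
  cat("Bootstrap clone inference\n")
  cat(sprintf("  %d sample(s), %d SNV(s), %d bootstrap replicate(s)\n",
              length(x$counts$sample_ids), length(x$counts$snv_ids),
              x$manifest$n_replicates_ok))
  cat(sprintf("  point estimate: %d clone(s)\n", nrow(x$point$genotypes)))
  sup <- x$consensus$support
  cat(sprintf("  consensus clones: %d (%d with >50%% support)\n",
              length(sup), sum(sup > 50)))
  if (!is.null(x$consensus_migration)) {
    cm <- x$consensus_migration
    cat(sprintf("  consensus migration paths (primary '%s'):\n", x$primary))
    for (i in seq_len(nrow(cm)))
      cat(sprintf("    %s -> %s  %5.1f%%  %s\n", cm$source[i],
                  cm$destination[i], cm$support_percent[i], cm$status[i]))
  }
  invisible(x)
}

#' @export
summary.cloneboot <- function(object, ...) {
  sup <- object$consensus$support
  amb <- rowMeans(is.na(object$consensus$genotypes))
  s <- list(
    n_samples = length(object$counts$sample_ids),
    n_snvs = length(object$counts$snv_ids),
    n_replicates = object$manifest$n_replicates_ok,
    n_point_clones = nrow(object$point$genotypes),
    n_consensus_clones = length(sup),
    support = stats::setNames(
      c(min(sup), stats::median(sup), max(sup)), c("min", "median", "max")),
    prop_low_support = mean(sup <= 10),
    mean_ambiguous_fraction = mean(amb),
    point_frequencies = object$point$frequencies,
    consensus_migration = object$consensus_migration)
  class(s) <- "summary.cloneboot"
  s
}

#' @export
print.summary.cloneboot <- function(x, ...) {
  cat("Bootstrap clone inference summary\n")
  cat(sprintf("  data: %d sample(s) x %d SNV(s); %d replicate(s)\n",
              x$n_samples, x$n_snvs, x$n_replicates))
  cat(sprintf("  point-estimate clones: %d\n", x$n_point_clones))
  cat(sprintf("  consensus clones: %d (support min/median/max = %.0f/%.0f/%.0f%%)\n",
              x$n_consensus_clones, x$support["min"], x$support["median"],
              x$support["max"]))
  cat(sprintf("  low-support (<=10%%) consensus clones: %.0f%%\n",
              100 * x$prop_low_support))
  cat(sprintf("  mean ambiguous fraction per consensus clone: %.3f\n",
              x$mean_ambiguous_fraction))
  cat("  point-estimate clone frequencies:\n")
  print(round(x$point_frequencies, 3))
  if (!is.null(x$consensus_migration)) {
    cat("  consensus migration history:\n")
    print(x$consensus_migration)
  }
  invisible(x)
}

#' @export
coef.cloneboot <- function(object, ...) object$point$frequencies

#' Plot a bootstrap clone inference
#'
#' Draws the point-estimate clone phylogeny; tips matching a consensus
#' clone (exactly, on unambiguous positions) are annotated with that
#' consensus clone's bootstrap support.
#'
#' @param x A `"cloneboot"` object.
#' @param ... Passed to `ape::plot.phylo`.
#' @export
plot.cloneboot <- function(x, ...) {
  tree <- x$point$tree
  sup <- rep(NA_real_, length(tree$tip.label))
  G <- x$point$genotypes
  C <- x$consensus$genotypes
  for (i in seq_along(tree$tip.label)) {
    lab <- tree$tip.label[i]
    if (!lab %in% rownames(G)) next
    for (j in seq_len(nrow(C))) {
      known <- !is.na(C[j, ])
      if (all(G[lab, known] == C[j, known])) {
        sup[i] <- x$consensus$support[j]; break
      }
    }
  }
  lab2 <- ifelse(is.na(sup), tree$tip.label,
                 sprintf("%s (%.0f%%)", tree$tip.label, sup))
  tree$tip.label <- lab2
  ape::plot.phylo(tree, ...)
  invisible(x)
}
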