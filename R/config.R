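#' Run configuration for the bootstrap clone-inference pipeline
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' The defaults are the operating values used throughout: 30 bootstrap
#' replicates; grouping of bootstrap clones that differ by at most one SNV
#' assignment; a strict >90% per-position majority for consensus base calls;
#' clones below 1% frequency in every sample discarded; clones reported as
#' present in a tumor site when their frequency exceeds 5%; and an SNV
#' quality filter requiring at least 50 reference reads and 2 variant reads
#' in some sample before the SNV is used to assess candidate clones.
#'
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param group_cutoff Maximum number of SNV-assignment differences allowed
#'   between a bootstrap clone and a group seed for the clone to join the
#'   group.
#' @param base_threshold Proportion of group members that must carry (or
#'   lack) a variant for the consensus state to be called; positions where
#'   neither state exceeds this proportion are ambiguous. Strict inequality.
#' @param prune_freq Clone-frequency threshold below which a clone is taken
#'   to be absent from a sample; clones absent everywhere are removed.
#'   Strict inequality ("lower than").
#' @param report_freq Clone frequency above which a clone counts as present
#'   in a tumor site for migration inference.
#' @param qc_min_ref,qc_min_alt Minimum reference / variant read counts (in
#'   at least one sample) for an SNV to enter candidate-clone quality
#'   assessment.
#' @param support_threshold_paths Bootstrap support (percent) at or above
#'   which a consensus migration path is drawn solid rather than tentative.
#' @param max_iter Iteration cap on the ancestral/hybrid clone search loop.
#' @param rng_seed Master seed for bootstrap resampling.
#'
#' @return A list of class `"cb_config"`.
#' @export
#' @examples
#' cfg <- cb_config(n_replicates = 10)
#' cfg$base_threshold
cb_config <- function(n_replicates = 30L,
                      group_cutoff = 1L,
                      base_threshold = 0.90,
                      prune_freq = 0.01,
                      report_freq = 0.05,
                      qc_min_ref = 50L,
                      qc_min_alt = 2L,
                      support_threshold_paths = 60,
                      max_iter = 10L,
                      rng_seed = 1L) {
  cfg <- list(
    n_replicates = as.integer(n_replicates),
    group_cutoff = as.integer(group_cutoff),
    base_threshold = base_threshold,
    prune_freq = prune_freq,
    report_freq = report_freq,
    qc_min_ref = as.integer(qc_min_ref),
    qc_min_alt = as.integer(qc_min_alt),
    support_threshold_paths = support_threshold_paths,
    max_iter = as.integer(max_iter),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$n_replicates >= 1L,
    cfg$group_cutoff >= 0L,
    cfg$base_threshold > 0, cfg$base_threshold <= 1,
    cfg$prune_freq > 0, cfg$prune_freq <= 1,
    cfg$report_freq > 0, cfg$report_freq <= 1,
    cfg$qc_min_ref >= 0L, cfg$qc_min_alt >= 0L,
    cfg$support_threshold_paths >= 0, cfg$support_threshold_paths <= 100,
    cfg$max_iter >= 1L
  )
  class(cfg) <- "cb_config"
  cfg
}

#' @export
print.cb_config <- function(x, ...) {
  cat("Bootstrap clone-inference configuration\n")
  for (nm in setdiff(names(x), NULL)) {
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
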