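#' Genotype error of inferred clones against simulated truth
#'
#' Each simulated clone is paired with its most similar inferred clone(s)
#' by Hamming distance (an inferred clone may be paired with several
#' simulated clones); ties are averaged. The per-clone error is the
#' (average) number of state differences divided by the sequence length.
#' Ambiguous inferred states (NA) count as half a mismatch by default, or
#' as a full mismatch with `ambiguous_cost = 1`.
#'
#' @param true_M Binary clones x SNVs matrix of simulated genotypes.
#' @param inferred_M Clones x SNVs matrix of inferred genotypes (NA =
#'   ambiguous).
#' @param ambiguous_cost Mismatch cost of an ambiguous inferred state
#'   (default 0.5).
#' @return A list of class `"ge_report"`: `per_clone` (named numeric GE per
#'   simulated clone), `dataset_ge` (mean over simulated clones), `pairing`
#'   (list: simulated clone -> inferred clone ids paired).
#' @export
genotype_error <- function(true_M, inferred_M, ambiguous_cost = 0.5) {
  L <- ncol(true_M)
  if (is.null(inferred_M) || nrow(inferred_M) == 0L) {
    warning("empty inferred clone set; genotype error is 1 for every clone")
    per <- stats::setNames(rep(1, nrow(true_M)), rownames(true_M))
    return(structure(list(per_clone = per, dataset_ge = 1,
                          pairing = list()), class = "ge_report"))
  }
  stopifnot(identical(colnames(true_M), colnames(inferred_M)))
  per <- numeric(nrow(true_M))
  pairing <- vector("list", nrow(true_M))
  names(per) <- names(pairing) <- rownames(true_M)
  for (i in seq_len(nrow(true_M))) {
    diffs <- vapply(seq_len(nrow(inferred_M)), function(j) {
      g <- inferred_M[j, ]
      amb <- is.na(g) | is.na(true_M[i, ])
      sum(g[!amb] != true_M[i, !amb]) + ambiguous_cost * sum(amb)
    }, numeric(1))
    best <- which(diffs == min(diffs))
    per[i] <- mean(diffs[best]) / L
    pairing[[i]] <- rownames(inferred_M)[best]
  }
  structure(list(per_clone = per, dataset_ge = mean(per), pairing = pairing),
            class = "ge_report")
}

#' @export
print.ge_report <- function(x, ...) {
  cat(sprintf("Genotype error: dataset mean %.4f over %d simulated clone(s)\n",
              x$dataset_ge, length(x$per_clone)))
  invisible(x)
}

#' Classify inferred migration paths against the truth
#'
#' Presence-set comparison of (source, destination) pairs: multiplicity is
#' collapsed.
#'
#' @param true_history,inferred_history Data frames with `source`,
#'   `destination` (or `"migration_history"` objects).
#' @return List `TP`, `FP`, `FN` (counts) and the corresponding path sets.
#' @export
classify_paths <- function(true_history, inferred_history) {
  get_keys <- function(h) {
    d <- if (inherits(h, "migration_history")) h$paths else h
    unique(paste(d$source, d$destination, sep = " -> "))
  }
  tk <- get_keys(true_history); ik <- get_keys(inferred_history)
  list(TP = length(intersect(ik, tk)),
       FP = length(setdiff(ik, tk)),
       FN = length(setdiff(tk, ik)),
       tp_paths = intersect(ik, tk),
       fp_paths = setdiff(ik, tk),
       fn_paths = setdiff(tk, ik))
}

#' Summarise accuracy by bootstrap-support bin
#'
#' Bins clone (or path) supports and summarises the genotype errors (or
#' TP/FP status) within each bin.
#'
#' @param support Numeric support values (percent).
#' @param ge Per-clone genotype errors aligned with `support` (for clone
#'   summaries), or NULL.
#' @param is_tp Logical TP flags aligned with `support` (for path
#'   summaries), or NULL.
#' @param breaks Bin edges (default `c(0, 10, 50, 100)`, i.e. <=10,
#'   (10,50], >50).
#' @return Data frame with one row per bin: `bin`, `n`, and either
#'   `median_ge`, `q1_ge`, `q3_ge` or `n_tp`, `n_fp`,
#'   `median_support_tp`, `median_support_fp`.
#' @export
support_accuracy_table <- function(support, ge = NULL, is_tp = NULL,
                                   breaks = c(0, 10, 50, 100)) {
  bins <- cut(support, breaks = breaks, include.lowest = TRUE)
  out <- data.frame(bin = levels(bins))
  out$n <- as.vector(table(bins))
  if (!is.null(ge)) {
    stats_by <- function(fun) vapply(levels(bins), function(b) {
      v <- ge[bins == b]
      if (length(v) == 0L) NA_real_ else fun(v)
    }, numeric(1))
    out$median_ge <- stats_by(stats::median)
    out$q1_ge <- stats_by(function(v) stats::quantile(v, 0.25, names = FALSE))
    out$q3_ge <- stats_by(function(v) stats::quantile(v, 0.75, names = FALSE))
  }
  if (!is.null(is_tp)) {
    out$n_tp <- vapply(levels(bins), function(b)
      sum(is_tp[bins == b]), numeric(1))
    out$n_fp <- vapply(levels(bins), function(b)
      sum(!is_tp[bins == b]), numeric(1))
  }
  out
}
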