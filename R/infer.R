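#' Pool candidate clones across samples and filter spurious candidates
#'
#' Candidate clones from all samples are pooled and exact duplicates
#' removed. Candidate quality is then assessed on the QC-passing SNVs only
#' — those with at least `qc_min_ref` reference reads and `qc_min_alt`
#' variant reads in at least one sample. Candidates that are not
#' distinguished from every other candidate by at least one QC-passing SNV
#' are collapsed (the first is kept), and candidates carrying no QC-passing
#' SNV at all are dropped.
#'
#' @param candidates List of candidate genotype matrices (one per sample),
#'   all over the same SNV universe.
#' @param counts The `read_counts` object the candidates came from.
#' @param config A [cb_config()].
#' @return A deduplicated, filtered binary genotype matrix. If filtering
#'   removes everything, falls back to the single clone carrying all SNVs,
#'   with a warning.
#' @export
pool_and_filter <- function(candidates, counts, config = cb_config()) {
  M <- do.call(rbind, candidates)
  if (is.null(M) || nrow(M) == 0L) stop("no candidate clones supplied")
  keys <- apply(M, 1, paste, collapse = "")
  M <- M[!duplicated(keys), , drop = FALSE]
  M <- M[rowSums(M) > 0, , drop = FALSE]

  qc <- qc_pass(counts, config)
  if (any(qc)) {
    Mq <- M[, qc, drop = FALSE]
    carries_qc <- rowSums(Mq) > 0
    qkeys <- apply(Mq, 1, paste, collapse = "")
    distinct_qc <- !duplicated(qkeys)
    keep <- carries_qc & distinct_qc
  } else {
    keep <- rep(TRUE, nrow(M))
  }
  if (!any(keep)) {
    warning("all candidate clones filtered; falling back to a single clone ",
            "carrying all SNVs")
    M <- matrix(1L, 1, ncol(M), dimnames = list("all_snv", colnames(M)))
    return(M)
  }
  M[keep, , drop = FALSE]
}

#' SNVs passing the read-count quality filter
#'
#' @param counts A `read_counts` object.
#' @param config A [cb_config()]; uses `qc_min_ref` and `qc_min_alt`.
#' @return Logical vector over SNVs.
#' @export
qc_pass <- function(counts, config = cb_config()) {
  apply(counts$ref >= config$qc_min_ref & counts$alt >= config$qc_min_alt,
        2, any)
}

#' Estimate clone frequencies by constrained regression
#'
#' Per sample, solves the relationship (1/2) f M = V for the clone
#' frequencies f by bounded nonnegative least squares: minimise
#' ||(1/2) M' f - v||_2 subject to f >= 0 and sum(f) <= 1, leaving any
#' remainder interpretable as normal-cell contamination. The sum constraint
#' is imposed through an explicit zero-genotype "normal" component and a
#' heavily weighted sum-to-one row, solved by an active-set NNLS; when an
#' exact nonnegative solution exists it is recovered exactly.
#'
#' @param M Binary clones x SNVs genotype matrix.
#' @param V Samples x SNVs VAF matrix.
#' @return Samples x clones frequency matrix.
#' @export
estimate_frequencies <- function(M, V) {
  nc <- nrow(M); ns <- nrow(V)
  if (ncol(M) != ncol(V)) stop("M and V disagree on the number of SNVs")
  if (nc > 1L && qr(M)$rank < nc)
    warning("rank-deficient genotype matrix; frequencies are a least-norm ",
            "solution among minimisers")
  w <- 1e3
  A <- rbind(cbind(0.5 * t(M), 0), w)  # extra column = normal-cell component
  f <- matrix(0, ns, nc, dimnames = list(rownames(V), rownames(M)))
  for (s in seq_len(ns)) {
    b <- c(V[s, ], w)
    sol <- nnls_solve(A, b)
    f[s, ] <- sol[seq_len(nc)]
  }
  f
}

fit_residual <- function(M, f, V) {
  sum((0.5 * f %*% M - V)^2)
}

#' Remove clones below the frequency threshold
#'
#' Frequencies strictly below `threshold` are zeroed (the clone is taken to
#' be absent from that sample); clones absent from every sample are
#' removed and frequencies re-estimated on the reduced genotype matrix.
#'
#' @param M Binary genotype matrix.
#' @param f Samples x clones frequency matrix.
#' @param V Samples x SNVs VAF matrix (for re-estimation).
#' @param threshold Frequency threshold in (0, 1).
#' @return List with pruned `M` and re-estimated `f`.
#' @export
prune_low_frequency <- function(M, f, V, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  f[f < threshold] <- 0
  present <- colSums(f) > 0
  if (!any(present)) {
    warning("all clones below the frequency threshold; keeping the single ",
            "highest-frequency clone")
    best <- which.max(apply(estimate_frequencies(M, V), 2, max))
    present[best] <- TRUE
  }
  if (all(present)) return(list(M = M, f = f))
  M2 <- M[present, , drop = FALSE]
  f2 <- estimate_frequencies(M2, V)
  f2[f2 < threshold] <- 0
  list(M = M2, f = f2)
}

# Deterministic 2-means on rows of a matrix: centers initialised at the
# farthest pair of points, then standard Lloyd iterations.
two_means <- function(X, max_iter = 50L) {
  n <- nrow(X)
  if (n < 2L) return(rep(1L, n))
  d <- as.matrix(stats::dist(X))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  centers <- X[c(ij[1], ij[2]), , drop = FALSE]
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d1 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- rowSums((X - matrix(centers[2, ], n, ncol(X), byrow = TRUE))^2)
    new_assign <- ifelse(d1 <= d2, 1L, 2L)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    if (all(assign == 1L) || all(assign == 2L)) break
    centers <- rbind(colMeans(X[assign == 1L, , drop = FALSE]),
                     colMeans(X[assign == 2L, , drop = FALSE]))
  }
  assign
}

#' Decompose potential hybrid clones
#'
#' SNVs with identical expected VAF profiles (the same carrying-clone set)
#' are split into two groups by their observed-VAF residual profiles across
#' samples (deterministic 2-means). For every clone carrying such a group,
#' alternate genotypes carrying only group A or only group B of the split
#' are appended to M; frequencies are re-estimated and only alternates
#' reaching the prune threshold in at least one sample are retained.
#'
#' @param M Binary genotype matrix.
#' @param V Samples x SNVs VAF matrix.
#' @param f Current frequency estimate for `M`.
#' @param threshold Frequency threshold for accepting an alternate clone.
#' @return Possibly augmented genotype matrix.
#' @export
decompose_hybrids <- function(M, V, f, threshold = 0.01) {
  E <- 0.5 * f %*% M
  carrier_key <- apply(M, 2, paste, collapse = "")
  groups <- split(seq_len(ncol(M)), carrier_key)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  new_rows <- list()
  for (g in groups) {
    if (all(colSums(M[, g, drop = FALSE]) == 0)) next
    R <- t(V[, g, drop = FALSE] - E[, g, drop = FALSE])  # SNVs x samples
    if (max(stats::dist(R)) < 1e-12) next
    split2 <- two_means(R)
    if (length(unique(split2)) < 2L) next
    gA <- g[split2 == 1L]; gB <- g[split2 == 2L]
    carriers <- which(M[, g[1]] == 1L)
    for (cl in carriers) {
      rowA <- M[cl, ]; rowA[gB] <- 0L
      rowB <- M[cl, ]; rowB[gA] <- 0L
      new_rows[[length(new_rows) + 1L]] <- rowA
      new_rows[[length(new_rows) + 1L]] <- rowB
    }
  }
  if (length(new_rows) == 0L) return(M)
  cand <- do.call(rbind, new_rows)
  keys <- apply(cand, 1, paste, collapse = "")
  have <- apply(M, 1, paste, collapse = "")
  cand <- cand[!(keys %in% have) & !duplicated(keys) & rowSums(cand) > 0,
               , drop = FALSE]
  if (nrow(cand) == 0L) return(M)
  nm <- character(nrow(cand))
  k <- 0L
  for (i in seq_len(nrow(cand))) {
    repeat {
      k <- k + 1L
      if (!paste0("hyb", k) %in% rownames(M)) break
    }
    nm[i] <- paste0("hyb", k)
  }
  rownames(cand) <- nm
  M2 <- rbind(M, cand)
  f2 <- estimate_frequencies(M2, V)
  keep_new <- apply(f2[, -seq_len(nrow(M)), drop = FALSE], 2, max) >= threshold
  rbind(M, cand[keep_new, , drop = FALSE])
}

#' Finalise a clone prediction
#'
#' Every SNV assigned to no clone is added (state 1) to the clone whose
#' expected-VAF profile across samples — half the clone's frequency vector
#' — is nearest in least squares to the SNV's observed VAFs; ties go to the
#' clone with the higher mean frequency. Frequencies are re-estimated and
#' the tree rebuilt on the final genotypes.
#'
#' @param M Binary genotype matrix.
#' @param f Samples x clones frequency matrix.
#' @param V Samples x SNVs VAF matrix.
#' @return A list of class `"clone_prediction"`: `genotypes`,
#'   `frequencies`, `tree`.
#' @export
finalize_prediction <- function(M, f, V) {
  unassigned <- which(colSums(M) == 0L)
  if (length(unassigned) > 0L) {
    expected <- 0.5 * f  # samples x clones: profile if the clone carried it
    for (j in unassigned) {
      err <- colSums((expected - V[, j])^2)
      best <- which(err <= min(err) + 1e-12)
      if (length(best) > 1L) best <- best[which.max(colMeans(f)[best])]
      M[best, j] <- 1L
    }
    f <- estimate_frequencies(M, V)
  }
  tree <- build_tree(M)
  structure(list(genotypes = M, frequencies = f, tree = tree),
            class = "clone_prediction")
}

#' @export
print.clone_prediction <- function(x, ...) {
  cat(sprintf("Clone prediction: %d clone(s), %d SNV(s), %d sample(s)\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$frequencies)))
  cat("Clone frequencies:\n")
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Infer clones from a multi-sample read-count table
#'
#' The full deconvolution engine. Per sample, SNVs are clustered by VAF and
#' candidate clones built by accumulating SNVs from the root cluster
#' downward; candidates are pooled across samples, deduplicated and
#' filtered; then the engine iterates clone-phylogeny construction,
#' ancestral-genotype search, constrained frequency estimation (the
#' (1/2) f M = V regression), low-frequency pruning and hybrid
#' decomposition until the clone set stabilises; finally unassigned SNVs
#' are attached to their nearest clone by VAF profile.
#'
#' Deterministic given its input: no random numbers are consumed.
#'
#' @param counts A `read_counts` object.
#' @param config A [cb_config()].
#' @param k_max Maximum clusters per sample for the VAF-clustering stage.
#' @param ccf Optional CCF matrix/vector; when given, VAFs are replaced by
#'   CCF/2 before inference (see [apply_ccf()]).
#' @return A `"clone_prediction"`: genotypes, frequencies, tree.
#' @export
#' @examples
#' truth <- simulate_truth(n_clones = 3, n_snvs = 12, n_samples = 3, seed = 7)
#' rc <- simulate_reads(truth, depth_mean = 500, seed = 8)
#' pred <- run_clonefinder_plus(rc)
#' pred
run_clonefinder_plus <- function(counts, config = cb_config(), k_max = 8L,
                                 ccf = NULL) {
  V <- suppressWarnings(vaf(counts))
  if (!is.null(ccf)) V <- apply_ccf(V, ccf)
  chains <- lapply(counts$sample_ids, function(s)
    suppressWarnings(
      cluster_sample(counts$alt[s, ], counts$ref[s, ], k_max = k_max,
                     sample_id = s)))
  cands <- lapply(chains, candidates_from_chain, all_snv_ids = counts$snv_ids)
  cands <- cands[vapply(cands, nrow, 1L) > 0]
  if (length(cands) == 0L) stop("no candidate clones in any sample")
  M <- pool_and_filter(cands, counts, config)

  for (it in seq_len(config$max_iter)) {
    keys_before <- sort(apply(M, 1, paste, collapse = ""))
    if (nrow(M) >= 2L) {
      tree <- build_tree(M)
      M <- infer_ancestral_clones(tree, M)
    }
    f <- estimate_frequencies(M, V)
    pruned <- prune_low_frequency(M, f, V, config$prune_freq)
    M <- pruned$M; f <- pruned$f
    M <- decompose_hybrids(M, V, f, config$prune_freq)
    f <- estimate_frequencies(M, V)
    pruned <- prune_low_frequency(M, f, V, config$prune_freq)
    M <- pruned$M; f <- pruned$f
    keys_after <- sort(apply(M, 1, paste, collapse = ""))
    if (identical(keys_before, keys_after)) break
  }
  if (it == config$max_iter)
    warning("clone search did not reach a fixpoint within ", config$max_iter,
            " iterations; returning the current clone set")
  finalize_prediction(M, f, V)
}
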