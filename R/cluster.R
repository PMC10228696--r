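#' Cluster the SNVs of one sample by VAF
#'
#' One-dimensional model-based clustering of a sample's variant read counts:
#' a binomial mixture over the observed (alt, total) pairs is fitted by EM
#' for 1..`k_max` components and the component count is chosen by BIC.
#' Clusters are ordered root-first by descending fitted VAF and linked into
#' a chain with one level of sibling branching: walking down the order, a
#' cluster becomes a *sibling* of the current chain tip when its CCF
#' (2 x VAF) still fits beside the tip's CCF inside their common parent's
#' CCF (the pigeonhole rule), and a *descendant* of the tip otherwise. A
#' single cluster is labelled monoclonal.
#'
#' Only SNVs with at least one variant read in the sample are clustered.
#'
#' @param alt,ref Per-SNV variant / reference read counts for one sample
#'   (named vectors; names are SNV ids).
#' @param k_max Maximum number of mixture components tried.
#' @param sample_id Label carried through to the result.
#' @param tol CCF slack used by the pigeonhole rule.
#' @return An object of class `"snv_chain"`: list with `sample_id` and
#'   `clusters`, an ordered list of `list(snv_ids, mean_vaf, parent,
#'   relationship)` where `parent` indexes into `clusters` (0 = root
#'   position) and `relationship` is one of `"monoclonal"`, `"root"`,
#'   `"ancestor-descendant"`, `"sibling"`.
#' @export
cluster_sample <- function(alt, ref, k_max = 8L, sample_id = "sample",
                           tol = 0.05) {
  tot <- alt + ref
  keep <- alt > 0 & tot > 0
  if (!any(keep)) {
    warning("sample ", sample_id, ": all VAFs zero; empty cluster chain")
    return(structure(list(sample_id = sample_id, clusters = list()),
                     class = "snv_chain"))
  }
  ids <- names(alt)[keep]
  a <- alt[keep]; n <- tot[keep]
  k_max <- min(k_max, length(a))
  fits <- lapply(seq_len(k_max), function(k) binom_mixture_em(a, n, k))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bic)]]
  assign <- best$assignment
  ks <- sort(unique(assign))
  clusters <- lapply(ks, function(k) {
    list(snv_ids = ids[assign == k], mean_vaf = best$p[k])
  })
  # order by descending VAF; ties by smallest member SNV id for stability
  first_id <- vapply(clusters, function(cl) min(cl$snv_ids), "")
  ord <- order(-vapply(clusters, `[[`, numeric(1), "mean_vaf"), first_id)
  clusters <- clusters[ord]

  nclust <- length(clusters)
  if (nclust == 1L) {
    clusters[[1]]$parent <- 0L
    clusters[[1]]$relationship <- "monoclonal"
  } else {
    ccf <- pmin(2 * vapply(clusters, `[[`, numeric(1), "mean_vaf"), 1)
    parent <- integer(nclust)
    parent[1] <- 0L
    clusters[[1]]$relationship <- "root"
    tip <- 1L
    for (i in 2:nclust) {
      gp <- parent[tip]
      sib_sum <- if (gp > 0L) sum(ccf[parent == gp]) else Inf
      if (gp > 0L && ccf[i] + sib_sum <= ccf[gp] + tol) {
        parent[i] <- gp
        clusters[[i]]$relationship <- "sibling"
      } else {
        parent[i] <- tip
        clusters[[i]]$relationship <- "ancestor-descendant"
        tip <- i
      }
    }
    for (i in seq_len(nclust)) clusters[[i]]$parent <- parent[i]
  }
  structure(list(sample_id = sample_id, clusters = clusters),
            class = "snv_chain")
}

# EM for a k-component binomial mixture; deterministic quantile init.
binom_mixture_em <- function(a, n, k, max_iter = 200L, eps = 1e-8) {
  v <- a / n
  m <- length(a)
  p <- stats::quantile(v, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dbinom(a, n, p[j], log = TRUE), numeric(m))
    logd <- matrix(logd, m, k)
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    g <- exp(logd - lse)
    ll <- sum(lse)
    w <- colMeans(g)
    p <- colSums(g * a) / pmax(colSums(g * n), 1e-12)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    if (abs(ll - ll_old) < eps) break
    ll_old <- ll
  }
  assignment <- max.col(g, ties.method = "first")
  bic <- -2 * ll + (2 * k - 1) * log(m)
  list(p = p, w = w, assignment = assignment, loglik = ll, bic = bic)
}

#' Candidate clone genotypes from a cluster chain
#'
#' One candidate clone per cluster: the clone for cluster c carries exactly
#' the SNVs of the clusters on the path from the root cluster to c. SNVs
#' not present in the sample are 0.
#'
#' @param chain An `"snv_chain"` from [cluster_sample()].
#' @param all_snv_ids Full SNV universe (column order of the result).
#' @return A binary candidate-genotype matrix (clones x SNVs); zero rows
#'   when the chain is empty.
#' @export
candidates_from_chain <- function(chain, all_snv_ids) {
  ncl <- length(chain$clusters)
  g <- matrix(0L, ncl, length(all_snv_ids),
              dimnames = list(NULL, all_snv_ids))
  if (ncl == 0L) return(g)
  for (i in seq_len(ncl)) {
    j <- i
    repeat {
      g[i, chain$clusters[[j]]$snv_ids] <- 1L
      j <- chain$clusters[[j]]$parent
      if (j == 0L) break
    }
  }
  rownames(g) <- paste0(chain$sample_id, "_c", seq_len(ncl))
  g
}
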