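#' Group near-identical clones across bootstrap replicates
#'
#' All clones from all replicates are pooled. Distinct genotypes are ranked
#' by how often they occur (ties broken lexicographically by genotype
#' string); group seeds are taken in that order, and a clone joins the
#' first group whose seed is within `cutoff` Hamming differences — provided
#' its own exact genotype occurs strictly less often than the seed's, so
#' noise variants are absorbed into a stable clone's group but two equally
#' stable clones are never merged. A replicate contributes at most once to
#' a group's support:
#' support = 100 x (number of replicates contributing at least one member) /
#' (number of replicates).
#'
#' @param clone_sets List (one element per replicate) of binary genotype
#'   matrices over a common SNV universe.
#' @param cutoff Maximum SNV differences from the group seed.
#' @return A list of class `"clone_groups"`; each element has `seed`
#'   (genotype vector), `members` (matrix), `member_replicates` (integer
#'   vector), `support` (percent).
#' @export
group_clones <- function(clone_sets, cutoff = 1L) {
  n_rep <- length(clone_sets)
  stopifnot(n_rep >= 1L)
  snvs <- colnames(clone_sets[[1]])
  pool <- do.call(rbind, clone_sets)
  rep_of <- rep(seq_len(n_rep), vapply(clone_sets, nrow, 1L))
  keys <- apply(pool, 1, paste, collapse = "")
  freq <- sort(table(keys), decreasing = TRUE)
  ord <- order(-as.vector(freq), names(freq))
  seed_keys <- names(freq)[ord]

  first_idx <- match(seed_keys, keys)
  seeds <- pool[first_idx, , drop = FALSE]
  nseed <- length(seed_keys)
  key_freq <- as.vector(freq)[match(keys, names(freq))]
  assigned <- rep(NA_integer_, nrow(pool))
  group_id <- 0L
  groups <- list()
  for (k in seq_len(nseed)) {
    todo <- which(is.na(assigned))
    if (length(todo) == 0L) break
    if (!is.na(assigned[first_idx[k]])) next  # seed already captured
    group_id <- group_id + 1L
    seed <- seeds[k, ]
    seed_freq <- key_freq[first_idx[k]]
    d <- colSums(abs(t(pool[todo, , drop = FALSE]) - seed))
    take <- todo[d <= cutoff &
                   (keys[todo] == seed_keys[k] | key_freq[todo] < seed_freq)]
    assigned[take] <- group_id
    reps <- unique(rep_of[take])
    groups[[group_id]] <- list(
      seed = seed,
      members = pool[take, , drop = FALSE],
      member_replicates = rep_of[take],
      support = 100 * length(reps) / n_rep)
  }
  attr(groups, "n_replicates") <- n_rep
  attr(groups, "snv_ids") <- snvs
  class(groups) <- "clone_groups"
  groups
}

#' @export
print.clone_groups <- function(x, ...) {
  sup <- vapply(x, `[[`, numeric(1), "support")
  cat(sprintf("%d clone group(s) over %d bootstrap replicate(s)\n",
              length(x), attr(x, "n_replicates")))
  cat(sprintf("  support: median %.0f%%, range %.0f-%.0f%%\n",
              stats::median(sup), min(sup), max(sup)))
  cat(sprintf("  groups with >50%% support: %d\n", sum(sup > 50)))
  invisible(x)
}

#' Consensus genotype of a clone group
#'
#' Per SNV position: state 1 when the variant is carried by more than
#' `base_threshold` of the member clones; state 0 when it is absent from
#' more than `base_threshold` of them; ambiguous (NA) otherwise. The
#' inequality is strict, so at threshold 0.9 a 9-of-10 position is
#' ambiguous.
#'
#' Each bootstrap replicate votes once: when a replicate contributed
#' several members to the group, only its representative — the member
#' closest to the group seed (ties broken lexicographically by genotype
#' string) — enters the per-position count, mirroring the
#' one-vote-per-replicate definition of group support.
#'
#' @param group One element of a [group_clones()] result.
#' @param base_threshold Proportion in (0, 1].
#' @return Integer genotype vector with NA marking ambiguous positions.
#' @export
consensus_sequence <- function(group, base_threshold = 0.90) {
  m <- group_representatives(group)
  p1 <- colMeans(m == 1L)
  out <- rep(NA_integer_, ncol(m))
  out[p1 > base_threshold] <- 1L
  out[(1 - p1) > base_threshold] <- 0L
  names(out) <- colnames(m)
  out
}

# One member per contributing replicate: the member nearest the group
# seed, ties broken by genotype string.
group_representatives <- function(group) {
  m <- group$members
  reps <- group$member_replicates
  if (is.null(reps) || !anyDuplicated(reps)) return(m)
  d <- colSums(abs(t(m) - group$seed))
  keys <- apply(m, 1, paste, collapse = "")
  keep <- vapply(unique(reps), function(r) {
    idx <- which(reps == r)
    idx[order(d[idx], keys[idx])][1]
  }, integer(1))
  m[keep, , drop = FALSE]
}

#' Consensus clones with bootstrap support
#'
#' Convenience wrapper: groups the bootstrap clones and returns the
#' consensus genotype and support of every group, ordered by descending
#' support.
#'
#' @param clone_sets List of per-replicate genotype matrices.
#' @param cutoff SNV-difference grouping cutoff.
#' @param base_threshold Consensus base-call threshold.
#' @return List with `genotypes` (consensus matrix, NA = ambiguous),
#'   `support` (percent per consensus clone), `groups` (the
#'   `clone_groups`).
#' @export
consensus_clones <- function(clone_sets, cutoff = 1L, base_threshold = 0.90) {
  groups <- group_clones(clone_sets, cutoff)
  cons <- t(vapply(groups, consensus_sequence,
                   integer(length(attr(groups, "snv_ids"))),
                   base_threshold = base_threshold))
  colnames(cons) <- attr(groups, "snv_ids")
  rownames(cons) <- paste0("consensus", seq_len(nrow(cons)))
  support <- vapply(groups, `[[`, numeric(1), "support")
  ord <- order(-support)
  list(genotypes = cons[ord, , drop = FALSE], support = support[ord],
       groups = groups[ord])
}
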