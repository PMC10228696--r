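# Small deterministic fixtures shared across tests.

toy_counts <- function() {
  ref <- matrix(c(90, 80,
                  70, 95,
                  60, 85), nrow = 2, ncol = 3,
                dimnames = list(c("P", "M1"), c("s1", "s2", "s3")))
  alt <- matrix(c(10, 20,
                  30,  5,
                  40, 15), nrow = 2, ncol = 3,
                dimnames = list(c("P", "M1"), c("s1", "s2", "s3")))
  read_count_table(ref, alt)
}

# chain with root cluster {s1, s2} and descendant {s3}
toy_chain <- function() {
  structure(list(
    sample_id = "P",
    clusters = list(
      list(snv_ids = c("s1", "s2"), mean_vaf = 0.5, parent = 0L,
           relationship = "root"),
      list(snv_ids = "s3", mean_vaf = 0.2, parent = 1L,
           relationship = "ancestor-descendant"))),
    class = "snv_chain")
}

# root cluster A = {s1}, siblings B = {s2} and C = {s3} under A
sibling_chain <- function() {
  structure(list(
    sample_id = "P",
    clusters = list(
      list(snv_ids = "s1", mean_vaf = 0.5, parent = 0L,
           relationship = "root"),
      list(snv_ids = "s2", mean_vaf = 0.2, parent = 1L,
           relationship = "ancestor-descendant"),
      list(snv_ids = "s3", mean_vaf = 0.15, parent = 1L,
           relationship = "sibling"))),
    class = "snv_chain")
}

# brute-force minimum-migration count over all internal labelings with the
# root fixed to the primary site; leaves carry exactly one site each
brute_force_migrations <- function(tree, leaf_sites, primary) {
  sites <- sort(unique(c(leaf_sites, primary)))
  nn <- tree$Nnode
  lab_tip <- match(leaf_sites[tree$tip.label], sites)
  grid <- if (nn > 1) {
    as.matrix(expand.grid(rep(list(seq_along(sites)), nn - 1)))
  } else {
    matrix(numeric(0), 1, 0)
  }
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- c(lab_tip, match(primary, sites), if (nn > 1) grid[g, ])
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# tip sets of every clade of a rooted tree, as sorted character vectors
tree_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  lapply(seq_len(tree$Nnode) + ntip, function(n)
    sort(ape::extract.clade(tree, n)$tip.label))
}
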