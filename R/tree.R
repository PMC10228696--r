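#' Build a clone phylogeny from a binary genotype matrix
#'
#' Neighbor-joining on pairwise Hamming distances between clone genotypes,
#' with an all-zero germline genotype appended and used to root the tree.
#' Clones are sorted canonically (by genotype string) before distance
#' computation so the topology does not depend on input row order.
#'
#' @param M Binary clones x SNVs genotype matrix with unique rows and
#'   rownames.
#' @return A rooted `ape::phylo` tree whose tips are the clone ids plus
#'   `"germline"`.
#' @export
build_tree <- function(M) {
  if (is.null(rownames(M))) rownames(M) <- paste0("clone", seq_len(nrow(M)))
  if ("germline" %in% rownames(M))
    M <- M[rownames(M) != "germline", , drop = FALSE]
  keys <- apply(M, 1, paste, collapse = "")
  if (anyDuplicated(keys))
    stop("identical genotype rows in M: ",
         paste(rownames(M)[duplicated(keys)], collapse = ", "))
  M <- M[order(keys), , drop = FALSE]
  G <- rbind(M, germline = 0L)
  if (nrow(G) == 2L) {
    tree <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      tip.label = rownames(G), Nnode = 1L,
      edge.length = c(sum(G[1, ] != G[2, ]), 0)),
      class = "phylo", order = "cladewise")
    return(tree)
  }
  d <- stats::dist(G, method = "manhattan")
  tree <- ape::nj(d)
  tree <- ape::root(tree, outgroup = "germline", resolve.root = TRUE)
  tree
}

#' Ancestral genotype reconstruction by parsimony
#'
#' Fitch parsimony per SNV on the rooted clone tree, with the root state
#' fixed to 0 (germline) and top-down ties resolved toward the parent's
#' state. Because the root is absent-for-everything, this resolves
#' ambiguity toward absence, i.e. toward later gain.
#'
#' @param tree Rooted `ape::phylo` with clone tips and a `"germline"` tip.
#' @param M Binary genotype matrix whose rownames cover all non-germline
#'   tips.
#' @return A (tips + internal nodes) x SNVs integer matrix of genotypes;
#'   rows 1..Ntip follow `tree$tip.label`, internal rows are named
#'   `node<k>`.
#' @export
fitch_genotypes <- function(tree, M) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nsnv <- ncol(M)
  G <- rbind(M, germline = 0L)
  tipG <- G[tree$tip.label, , drop = FALSE]

  # candidate sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  sets <- matrix(0L, ntip + nnode, nsnv)
  sets[seq_len(ntip), ] <- ifelse(tipG == 1L, 2L, 1L)

  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    if (all(sets[par, ] == 0L)) {
      sets[par, ] <- sets[ch, ]
    } else {
      inter <- bitwAnd(sets[par, ], sets[ch, ])
      uni <- bitwOr(sets[par, ], sets[ch, ])
      sets[par, ] <- ifelse(inter > 0L, inter, uni)
    }
  }

  state <- matrix(NA_integer_, ntip + nnode, nsnv)
  root <- ntip + 1L
  state[root, ] <- 0L  # germline root
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    par <- pre$edge[i, 1]; ch <- pre$edge[i, 2]
    s <- sets[ch, ]
    ps <- state[par, ]
    pmask <- ifelse(ps == 1L, 2L, 1L)
    keep_parent <- bitwAnd(s, pmask) > 0L
    state[ch, ] <- ifelse(keep_parent, ps, ifelse(bitwAnd(s, 1L) > 0L, 0L, 1L))
  }
  rownames(state) <- c(tree$tip.label, paste0("node", seq_len(nnode)))
  colnames(state) <- colnames(M)
  state
}

#' Add missing ancestral clones inferred at internal nodes
#'
#' Internal-node genotypes from [fitch_genotypes()] that are not already
#' present in M (and are not the germline all-zero state) are appended as
#' new candidate clones.
#'
#' @param tree Rooted clone phylogeny.
#' @param M Binary genotype matrix.
#' @return M with any new ancestral genotypes appended (rownames
#'   `anc<k>`).
#' @export
infer_ancestral_clones <- function(tree, M) {
  st <- fitch_genotypes(tree, M)
  ntip <- length(tree$tip.label)
  internal <- st[-seq_len(ntip), , drop = FALSE]
  have <- apply(M, 1, paste, collapse = "")
  cand <- unique(internal)
  keys <- apply(cand, 1, paste, collapse = "")
  new <- cand[!(keys %in% have) & rowSums(cand) > 0, , drop = FALSE]
  if (nrow(new) == 0L) return(M)
  rownames(new) <- paste0("anc", seq.int(nrow(new)))
  # avoid rowname clashes with earlier ancestral additions
  k <- 1L
  for (i in seq_len(nrow(new))) {
    while (rownames(new)[i] %in% rownames(M)) {
      rownames(new)[i] <- paste0("anc", k <- k + 1L)
    }
  }
  rbind(M, new)
}

#' SNV gains along each branch of a clone phylogeny
#'
#' Assigns each SNV to the branch(es) where it switches from absent in the
#' parent genotype to present in the child. Under a perfect phylogeny each
#' SNV maps to exactly one branch; losses (1 -> 0) violate the gain-only
#' clone model and are logged as warnings, not errors.
#'
#' @param tree Rooted clone phylogeny.
#' @param M Binary genotype matrix for the tips.
#' @return A data frame with one row per edge: `parent`, `child` (node
#'   numbers), `child_label`, and a list-column `gained` of SNV ids.
#' @export
branch_gains <- function(tree, M) {
  st <- fitch_genotypes(tree, M)
  labels <- rownames(st)
  edges <- tree$edge
  gained <- vector("list", nrow(edges))
  losses <- 0L
  for (i in seq_len(nrow(edges))) {
    pg <- st[edges[i, 1], ]; cg <- st[edges[i, 2], ]
    gained[[i]] <- colnames(M)[pg == 0L & cg == 1L]
    losses <- losses + sum(pg == 1L & cg == 0L)
  }
  if (losses > 0L)
    warning(losses, " SNV state loss(es) along branches; ",
            "counted as zero gain (gain-only model)")
  out <- data.frame(parent = edges[, 1], child = edges[, 2],
                    child_label = labels[edges[, 2]])
  out$gained <- gained
  out
}
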