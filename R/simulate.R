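#' Simulate a tumor clone phylogeny, migration history and clone
#' frequencies
#'
#' Emulates multi-tumor metastatic progression: a random rooted clone tree
#' is grown by uniform attachment; SNVs are distributed over the tree's
#' branches (at least one per branch, remainder multinomial) so genotypes
#' obey a perfect phylogeny; tumor sites are seeded by migrations along the
#' tree — each metastatic site is founded by one clone lineage
#' (monoclonal) or several (polyclonal), with the founder's parent's site
#' as migration source; and per-site clone frequencies are drawn from a
#' symmetric Dirichlet over the clones resident at the site.
#'
#' @param n_clones Number of tumor clones (>= 2); genotypes are unique.
#' @param n_snvs Number of SNVs (>= n_clones, one or more per branch).
#' @param n_samples Number of tumor samples = sites (1 primary +
#'   metastases).
#' @param seeding `"monoclonal"` (one founder per metastasis) or
#'   `"polyclonal"` (two or more founders).
#' @param driver_rate Per-SNV probability of a driver flag on ordinary
#'   branches.
#' @param driver_enrichment Multiplier on `driver_rate` for SNVs on
#'   migration (founder) branches.
#' @param seed RNG seed.
#' @return An object of class `"sim_truth"`: `tree`, `genotypes`
#'   (clones x SNVs), `frequencies` (sites x clones, rows summing to 1 over
#'   resident clones), `history` (data frame `source`, `destination`),
#'   `clone_sites` (named site per clone), `driver_flags`, `primary`,
#'   `seeding`.
#' @export
#' @examples
#' truth <- simulate_truth(n_clones = 6, n_snvs = 30, n_samples = 5, seed = 1)
#' truth$history
simulate_truth <- function(n_clones, n_snvs, n_samples,
                           seeding = c("monoclonal", "polyclonal"),
                           driver_rate = 0.05, driver_enrichment = 4,
                           seed = 1L) {
  seeding <- match.arg(seeding)
  if (n_clones < 2L) stop("need at least 2 clones")
  if (n_snvs < n_clones)
    stop("need n_snvs >= n_clones so every branch carries a mutation")
  if (n_samples < 2L) stop("need a primary plus at least one metastasis")
  n_meta <- n_samples - 1L
  founders_per_site <- if (seeding == "monoclonal") 1L else 2L
  if (n_clones < 1L + n_meta * founders_per_site)
    stop("not enough clones to found ", n_meta, " metastases with ",
         founders_per_site, " founder(s) each")
  set.seed(as.integer(seed))

  # clone tree by uniform attachment; clone 1 is the founder under germline
  parent <- integer(n_clones)
  parent[1] <- 0L
  for (i in seq_len(n_clones)[-1]) parent[i] <- sample.int(i - 1L, 1L)

  # >= 1 SNV per branch (branch i leads to clone i)
  extra <- stats::rmultinom(1, n_snvs - n_clones, rep(1, n_clones))[, 1]
  per_branch <- 1L + extra
  branch_of_snv <- rep(seq_len(n_clones), per_branch)
  snv_ids <- paste0("snv", seq_len(n_snvs))

  genotypes <- matrix(0L, n_clones, n_snvs,
                      dimnames = list(paste0("C", seq_len(n_clones)), snv_ids))
  for (i in seq_len(n_clones)) {
    j <- i
    repeat {
      genotypes[i, branch_of_snv == j] <- 1L
      j <- parent[j]
      if (j == 0L) break
    }
  }

  # migrations: founders chosen among non-root clones, each founding clone
  # moves (with its descendants, until overridden) to its metastasis
  sites <- c("P", paste0("M", seq_len(n_meta)))
  candidates <- sample(seq_len(n_clones)[-1])  # random order, root stays
  founders <- list()
  idx <- 1L
  for (m in seq_len(n_meta)) {
    founders[[m]] <- candidates[idx:(idx + founders_per_site - 1L)]
    idx <- idx + founders_per_site
  }
  site_of <- rep(NA_character_, n_clones)
  site_of[1] <- "P"
  founder_site <- rep(NA_character_, n_clones)
  for (m in seq_len(n_meta)) founder_site[founders[[m]]] <- sites[m + 1L]
  # preorder: parents before children (guaranteed since parent[i] < i)
  for (i in seq_len(n_clones)[-1]) {
    site_of[i] <- if (!is.na(founder_site[i])) founder_site[i]
                  else site_of[parent[i]]
  }
  history <- do.call(rbind, lapply(seq_len(n_meta), function(m) {
    data.frame(source = site_of[parent[founders[[m]]]],
               destination = sites[m + 1L])
  }))
  rownames(history) <- NULL

  frequencies <- matrix(0, n_samples, n_clones,
                        dimnames = list(sites, rownames(genotypes)))
  for (s in sites) {
    resident <- which(site_of == s)
    w <- stats::rgamma(length(resident), shape = 1)
    frequencies[s, resident] <- w / sum(w)
  }

  is_migration_branch <- seq_len(n_clones) %in% unlist(founders)
  rate <- ifelse(is_migration_branch[branch_of_snv],
                 pmin(driver_rate * driver_enrichment, 1), driver_rate)
  driver_flags <- stats::setNames(stats::runif(n_snvs) < rate, snv_ids)

  tree <- build_tree(genotypes)
  structure(list(tree = tree, genotypes = genotypes,
                 frequencies = frequencies, history = history,
                 clone_sites = stats::setNames(site_of, rownames(genotypes)),
                 driver_flags = driver_flags, primary = "P",
                 seeding = seeding),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated tumor: %d clone(s), %d SNV(s), %d site(s), %s seeding\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$frequencies),
              x$seeding))
  cat(sprintf("  true migration paths: %s\n",
              paste(paste0(x$history$source, "->", x$history$destination),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate bulk-sequencing read counts from a simulated truth
#'
#' Per (sample, SNV): a total depth is drawn (negative binomial by default,
#' or uniform over `depth_range`), the expected VAF is half the summed
#' frequency of the clones carrying the SNV in that sample (times purity),
#' and the variant read count is binomial at that VAF.
#'
#' @param truth A `"sim_truth"` object.
#' @param depth_mean,depth_dispersion Negative-binomial depth model (mean /
#'   size); used when `depth_range` is NULL. Depths are floored at 1 read.
#' @param depth_range Optional `c(min, max)` for uniform depths instead.
#' @param purity Tumor purity scaling all expected VAFs (default 1).
#' @param seed RNG seed.
#' @return A `read_counts` object.
#' @export
simulate_reads <- function(truth, depth_mean = 100, depth_dispersion = 5,
                           depth_range = NULL, purity = 1, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(as.integer(seed))
  f <- truth$frequencies
  M <- truth$genotypes
  ev <- 0.5 * purity * (f %*% M)  # sites x SNVs expected VAF
  n <- length(ev)
  depth <- if (is.null(depth_range)) {
    pmax(1L, stats::rnbinom(n, mu = depth_mean, size = depth_dispersion))
  } else {
    # index into the range explicitly: sample(x, ...) on a length-1 x
    # would sample from 1:x
    rng <- seq.int(depth_range[1], depth_range[2])
    rng[sample.int(length(rng), n, replace = TRUE)]
  }
  alt <- stats::rbinom(n, depth, as.vector(ev))
  altm <- matrix(alt, nrow(ev), ncol(ev), dimnames = dimnames(ev))
  refm <- matrix(depth, nrow(ev), ncol(ev), dimnames = dimnames(ev)) - altm
  suppressWarnings(read_count_table(refm, altm))
}
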