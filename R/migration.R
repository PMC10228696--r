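#' Clone-to-site occupancy from a frequency matrix
#'
#' A clone occupies a tumor site when its estimated frequency there exceeds
#' the reporting threshold (strictly).
#'
#' @param f Samples(sites) x clones frequency matrix.
#' @param report_freq Reporting threshold (default 0.05).
#' @return Named list: clone id -> character vector of site ids.
#' @export
occupancy_from_frequencies <- function(f, report_freq = 0.05) {
  occ <- lapply(colnames(f), function(cl) rownames(f)[f[, cl] > report_freq])
  names(occ) <- colnames(f)
  occ
}

#' Infer a minimum-migration history for a clone phylogeny
#'
#' Sankoff dynamic programming with unit cost for site changes labels every
#' node of the clone phylogeny with a tumor site; the root (germline) is
#' fixed to the primary site. A clone occupying k sites contributes as k
#' co-located copies, so its node pays cost (k - 1) when labelled with one
#' of its sites and k otherwise, and emits one migration path per occupied
#' site other than its own label. Every tree edge whose endpoint labels
#' differ emits one (source, destination) path. Ties during traceback are
#' broken in favour of the parent's label, which favours fewer distinct
#' migration sources.
#'
#' @param tree Rooted clone phylogeny (tips: clone ids + `"germline"`).
#' @param occupancy Named list clone id -> sites, as from
#'   [occupancy_from_frequencies()]. Clones occupying no site are treated
#'   as unconstrained.
#' @param primary Primary tumor site id.
#' @return An object of class `"migration_history"`: list with `paths`
#'   (data frame `source`, `destination`, one row per migration event, plus
#'   `edge` giving the emitting child node or NA for co-location paths),
#'   `node_sites` (named site label per tree node), `n_migrations`.
#' @export
infer_history <- function(tree, occupancy, primary) {
  tips <- tree$tip.label
  clones <- setdiff(tips, "germline")
  occupancy <- occupancy[intersect(names(occupancy), clones)]
  sites <- sort(unique(c(primary, unlist(occupancy))))
  ns <- length(sites)
  ntip <- length(tips)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  BIG <- 1e9

  cost <- matrix(0, ntot, ns, dimnames = list(NULL, sites))
  for (i in seq_len(ntip)) {
    lab <- tips[i]
    if (lab == "germline") {
      cost[i, ] <- BIG; cost[i, primary] <- 0
    } else {
      occ <- occupancy[[lab]]
      if (length(occ) == 0L) {
        cost[i, ] <- 0
      } else {
        cost[i, ] <- length(occ) - as.numeric(sites %in% occ)
      }
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    trans <- vapply(seq_len(ns), function(s)
      min(cost[ch, ] + (seq_len(ns) != s)), numeric(1))
    cost[par, ] <- cost[par, ] + trans
  }

  root <- ntip + 1L
  label <- rep(NA_integer_, ntot)
  label[root] <- match(primary, sites)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    par <- pre$edge[i, 1]; ch <- pre$edge[i, 2]
    pl <- label[par]
    tot <- cost[ch, ] + (seq_len(ns) != pl)
    best <- which(tot == min(tot))
    if (ch <= ntip && tips[ch] != "germline") {
      # at a clone tip, prefer one of the clone's own sites among the
      # minima so migrations attach to the branch leading to the clone
      occ_idx <- which(sites %in% occupancy[[tips[ch]]])
      occ_best <- intersect(best, occ_idx)
      if (length(occ_best) > 0L) best <- occ_best
    }
    label[ch] <- if (pl %in% best) pl else best[1]
  }

  paths <- list()
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    if (label[par] != label[ch]) {
      paths[[length(paths) + 1L]] <- data.frame(
        source = sites[label[par]], destination = sites[label[ch]],
        edge = i)
    }
  }
  # co-location paths: a clone present at sites other than its node label
  for (i in seq_len(ntip)) {
    lab <- tips[i]
    if (lab == "germline") next
    occ <- occupancy[[lab]]
    extra <- setdiff(occ, sites[label[i]])
    for (e in extra) {
      paths[[length(paths) + 1L]] <- data.frame(
        source = sites[label[i]], destination = e, edge = NA_integer_)
    }
  }
  paths <- if (length(paths)) do.call(rbind, paths) else
    data.frame(source = character(), destination = character(),
               edge = integer())
  node_sites <- sites[label]
  names(node_sites) <- c(tips, paste0("node", seq_len(nnode)))
  structure(list(paths = paths, node_sites = node_sites,
                 n_migrations = nrow(paths), primary = primary),
            class = "migration_history")
}

#' @export
print.migration_history <- function(x, ...) {
  cat(sprintf("Migration history: %d path(s), primary site '%s'\n",
              nrow(x$paths), x$primary))
  if (nrow(x$paths) > 0) {
    tab <- table(paste0(x$paths$source, " -> ", x$paths$destination))
    for (nm in names(tab))
      cat(sprintf("  %s x%d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Map mutations (and drivers) onto migration paths
#'
#' SNVs are placed on branches by ancestral genotype reconstruction (gains
#' parent 0 -> child 1); each migration path emitted by a branch is
#' annotated with that branch's total mutation count and driver count.
#' Co-location paths (same clone in two sites) carry no branch and are
#' annotated with zero mutations. The driver rate is drivers / mutations,
#' undefined (NA) for paths without mutations, which are excluded from
#' rate summaries.
#'
#' @param tree Rooted clone phylogeny.
#' @param M Binary tip genotype matrix.
#' @param history A `"migration_history"` for this tree.
#' @param driver_flags Named logical vector over SNV ids (default: none are
#'   drivers).
#' @return Data frame: `source`, `destination`, `n_mutations`, `n_drivers`,
#'   `driver_rate`.
#' @export
map_mutations_to_paths <- function(tree, M, history, driver_flags = NULL) {
  if (is.null(driver_flags)) {
    driver_flags <- stats::setNames(rep(FALSE, ncol(M)), colnames(M))
  }
  gains <- suppressWarnings(branch_gains(tree, M))
  p <- history$paths
  n_mut <- integer(nrow(p)); n_drv <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (!is.na(p$edge[i])) {
      g <- gains$gained[[p$edge[i]]]
      n_mut[i] <- length(g)
      n_drv[i] <- sum(driver_flags[g], na.rm = TRUE)
    }
  }
  data.frame(source = p$source, destination = p$destination,
             n_mutations = n_mut, n_drivers = n_drv,
             driver_rate = ifelse(n_mut > 0, n_drv / n_mut, NA_real_))
}

#' Consensus migration history across bootstrap replicates
#'
#' Pools the migration paths of all replicate histories. The support of a
#' path is the percentage of replicates whose history contains it. Paths
#' with support at or above `threshold` are retained as solid; then, while
#' any tumor site observed in any replicate remains unreachable from the
#' primary, the highest-supported remaining path that extends the reachable
#' set is added as tentative.
#'
#' @param histories List of `"migration_history"` objects (or data frames
#'   with `source`/`destination`), one per replicate.
#' @param primary Primary site id.
#' @param threshold Solid-path support threshold in percent (default 60).
#' @return Data frame `source`, `destination`, `support_percent`, `status`
#'   (`"solid"`/`"tentative"`), sorted by descending support.
#' @export
consensus_history <- function(histories, primary, threshold = 60) {
  n_rep <- length(histories)
  stopifnot(n_rep >= 1L)
  dfs <- lapply(histories, function(h)
    if (inherits(h, "migration_history")) h$paths else h)
  keys_by_rep <- lapply(dfs, function(d)
    unique(paste(d$source, d$destination, sep = "\r")))
  all_keys <- sort(unique(unlist(keys_by_rep)))
  if (length(all_keys) == 0L)
    return(data.frame(source = character(), destination = character(),
                      support_percent = numeric(), status = character()))
  support <- vapply(all_keys, function(k)
    100 * sum(vapply(keys_by_rep, function(x) k %in% x, TRUE)) / n_rep,
    numeric(1))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  src <- vapply(parts, `[[`, "", 1)
  dst <- vapply(parts, `[[`, "", 2)
  ord <- order(-support, src, dst)
  src <- src[ord]; dst <- dst[ord]; support <- support[ord]

  sites <- unique(c(primary, src, dst))
  chosen <- support >= threshold
  status <- ifelse(chosen, "solid", NA_character_)
  reachable <- function(sel) {
    r <- primary
    repeat {
      add <- unique(dst[sel & src %in% r & !(dst %in% r)])
      if (length(add) == 0L) break
      r <- c(r, add)
    }
    r
  }
  repeat {
    r <- reachable(chosen)
    missing <- setdiff(sites, r)
    if (length(missing) == 0L) break
    cand <- which(!chosen & src %in% r & dst %in% missing)
    if (length(cand) == 0L)
      cand <- which(!chosen & dst %in% missing)
    if (length(cand) == 0L) break  # disconnected pool; nothing to add
    pick <- cand[1]  # already in descending-support order
    chosen[pick] <- TRUE
    status[pick] <- "tentative"
  }
  out <- data.frame(source = src[chosen], destination = dst[chosen],
                    support_percent = support[chosen],
                    status = status[chosen])
  rownames(out) <- NULL
  out
}

#' Compare driver mutation load between primary- and metastasis-sourced
#' migration paths
#'
#' For every replicate, computes the mean driver count per path and the
#' mean driver rate (drivers / mutations; paths without mutations are
#' excluded) separately for paths whose source is the primary site and for
#' paths sourced from metastatic sites, then compares the two classes
#' across replicates with Welch's two-sample t-test.
#'
#' @param annotations List (one per replicate) of path-annotation data
#'   frames from [map_mutations_to_paths()].
#' @param primary Primary site id.
#' @return List with per-replicate class means (`per_replicate`), and
#'   `count_test` / `rate_test`, each a list `t`, `p_value` (NA when a
#'   class is empty; for zero-variance data, t is 0/Inf with p 1/~0).
#' @export
compare_driver_rates <- function(annotations, primary) {
  per_rep <- do.call(rbind, lapply(seq_along(annotations), function(r) {
    a <- annotations[[r]]
    cls <- ifelse(a$source == primary, "primary", "metastatic")
    mk <- function(class) {
      sel <- cls == class
      data.frame(
        replicate = r, class = class,
        mean_driver_count = if (any(sel)) mean(a$n_drivers[sel]) else NA_real_,
        mean_driver_rate =
          if (any(sel & a$n_mutations > 0))
            mean(a$driver_rate[sel & a$n_mutations > 0]) else NA_real_)
    }
    rbind(mk("primary"), mk("metastatic"))
  }))
  run_test <- function(col) {
    x <- per_rep[per_rep$class == "primary", col]
    y <- per_rep[per_rep$class == "metastatic", col]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      return(list(t = NA_real_, p_value = NA_real_))
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) return(list(t = 0, p_value = 1))
      warning("zero variance in both path classes; reporting infinite t")
      return(list(t = sign(mean(x) - mean(y)) * Inf, p_value = 0))
    }
    tt <- stats::t.test(x, y)
    list(t = unname(tt$statistic), p_value = tt$p.value)
  }
  list(per_replicate = per_rep,
       count_test = run_test("mean_driver_count"),
       rate_test = run_test("mean_driver_rate"))
}
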