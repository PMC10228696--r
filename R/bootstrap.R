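#' Resample the reads at one position with replacement
#'
#' Draws `ref + alt` reads with replacement from the observed two-class read
#' pool. Because there are only two read classes, the number of variant
#' reads in the resample is exactly a binomial draw with size `ref + alt`
#' and success probability `alt / (ref + alt)`; the total is preserved by
#' construction.
#'
#' @param ref,alt Non-negative read counts (vectorised).
#' @return A list with resampled `ref` and `alt` vectors; totals unchanged.
#' @export
#' @examples
#' set.seed(1)
#' resample_position(16, 4)
resample_position <- function(ref, alt) {
  tot <- ref + alt
  if (any(tot == 0))
    warning("zero-total position(s) returned unchanged")
  alt2 <- integer(length(tot))
  nz <- tot > 0
  alt2[nz] <- stats::rbinom(sum(nz), tot[nz], alt[nz] / tot[nz])
  list(ref = as.integer(tot - alt2), alt = as.integer(alt2))
}

#' Generate one bootstrap replicate of a read-count table
#'
#' Every (sample, SNV) cell is resampled independently; cell totals are
#' preserved exactly. The replicates of all samples of a patient together
#' form one pseudo-multi-tumor dataset.
#'
#' @param x A `read_counts` object.
#' @return A `read_counts` object with identical samples, SNVs and per-cell
#'   totals.
#' @export
make_replicate <- function(x) {
  stopifnot(inherits(x, "read_counts"))
  tot <- x$ref + x$alt
  p <- ifelse(tot > 0, x$alt / pmax(tot, 1L), 0)
  alt2 <- matrix(stats::rbinom(length(tot), as.vector(tot), as.vector(p)),
                 nrow(tot), ncol(tot), dimnames = dimnames(tot))
  y <- x
  y$alt <- alt2
  y$ref <- tot - alt2
  storage.mode(y$alt) <- "integer"; storage.mode(y$ref) <- "integer"
  y
}

#' Generate a set of bootstrap replicates
#'
#' Replicate r is drawn under a seed derived deterministically from the
#' master seed and r, so individual replicates are reproducible regardless
#' of generation order.
#'
#' @param x A `read_counts` object.
#' @param n Number of replicates (default 30).
#' @param seed Master seed.
#' @return A list of class `"replicate_set"`: elements `replicates` (list of
#'   `read_counts`) and `seeds` (integer vector).
#' @export
make_replicate_set <- function(x, n = 30L, seed = 1L) {
  stopifnot(n >= 1L)
  seeds <- derive_seeds(seed, n)
  reps <- lapply(seeds, function(s) {
    withr_seed(s)
    make_replicate(x)
  })
  structure(list(replicates = reps, seeds = seeds), class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Bootstrap replicate set: %d replicate(s) of a %d x %d table\n",
              length(x$replicates),
              length(x$replicates[[1]]$sample_ids),
              length(x$replicates[[1]]$snv_ids)))
  invisible(x)
}

# Deterministic per-replicate seeds below 2^31, derived from the master seed.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

withr_seed <- function(s) set.seed(as.integer(s))

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
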