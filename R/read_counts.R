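#' Construct a per-position read-count table
#'
#' The substrate of the whole pipeline: for every (sample, SNV) pair, the
#' number of sequencing reads without (`ref`) and with (`alt`) the variant.
#'
#' SNVs whose total read count is zero in every sample carry no information
#' and are dropped with a warning. SNVs with no variant reads anywhere are
#' retained (they can arise legitimately in bootstrap replicates, where
#' resampling may lose all variant reads at a position).
#'
#' @param ref,alt Integer matrices (samples x SNVs) of reference / variant
#'   read counts, with matching dimnames.
#' @return An object of class `"read_counts"`: a list with elements `ref`,
#'   `alt` (samples x SNVs integer matrices), `sample_ids`, `snv_ids`.
#' @export
#' @examples
#' rc <- read_count_table(
#'   ref = matrix(c(90, 80, 70, 95), 2, 2,
#'                dimnames = list(c("P", "M1"), c("s1", "s2"))),
#'   alt = matrix(c(10, 20, 30, 5), 2, 2,
#'                dimnames = list(c("P", "M1"), c("s1", "s2"))))
#' vaf(rc)
read_count_table <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt)))
    stop("ref and alt count matrices must have identical dimensions")
  if (is.null(rownames(ref)))
    rownames(ref) <- rownames(alt) <- paste0("S", seq_len(nrow(ref)))
  if (is.null(colnames(ref)))
    colnames(ref) <- colnames(alt) <- paste0("snv", seq_len(ncol(ref)))
  if (anyDuplicated(colnames(ref)))
    stop("duplicate SNV ids: ",
         paste(unique(colnames(ref)[duplicated(colnames(ref))]), collapse = ", "))
  if (any(ref < 0) || any(alt < 0)) {
    bad <- unique(colnames(ref)[colSums(ref < 0 | alt < 0) > 0])
    stop("negative read counts at SNV(s): ", paste(bad, collapse = ", "))
  }
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  dimnames(alt) <- dimnames(ref)
  tot0 <- colSums(ref + alt) == 0
  if (any(tot0)) {
    warning("dropping ", sum(tot0), " SNV(s) with zero total reads in all samples: ",
            paste(colnames(ref)[tot0], collapse = ", "))
    ref <- ref[, !tot0, drop = FALSE]
    alt <- alt[, !tot0, drop = FALSE]
  }
  if (ncol(ref) == 0L) stop("no SNVs left after dropping zero-coverage rows")
  structure(list(ref = ref, alt = alt,
                 sample_ids = rownames(ref), snv_ids = colnames(ref)),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("Read-count table: %d sample(s) x %d SNV(s)\n",
              length(x$sample_ids), length(x$snv_ids)))
  cat("  samples:", paste(utils::head(x$sample_ids, 8), collapse = ", "),
      if (length(x$sample_ids) > 8) "..." else "", "\n")
  tot <- x$ref + x$alt
  cat(sprintf("  depth per cell: %d-%d (median %.0f)\n",
              min(tot), max(tot), stats::median(tot)))
  invisible(x)
}

#' Variant allele frequencies
#'
#' VAF = alt / (alt + ref) per cell; cells with zero total depth get VAF 0
#' with a warning (they carry no evidence either way).
#'
#' @param x A `read_counts` object.
#' @return A samples x SNVs numeric matrix in \[0, 1\].
#' @export
vaf <- function(x) {
  stopifnot(inherits(x, "read_counts"))
  tot <- x$ref + x$alt
  v <- matrix(0, nrow(tot), ncol(tot), dimnames = dimnames(tot))
  nz <- tot > 0
  v[nz] <- x$alt[nz] / tot[nz]
  if (any(!nz))
    warning(sum(!nz), " cell(s) with zero depth; VAF set to 0")
  v
}

#' Read a tab-separated read-count table
#'
#' The canonical dialect is a single TSV with an `snv_id` column followed by
#' interleaved `<sample>:ref` / `<sample>:alt` column pairs. A two-file
#' dialect (one TSV of reference counts, one of variant counts, both
#' samples-in-columns) is accepted via `dialect = "two-file"`, in which case
#' `path` is the reference-count file and `alt_path` the variant-count file.
#'
#' @param path Path to the count table (or reference-count table).
#' @param dialect `"interleaved"` (default) or `"two-file"`.
#' @param alt_path Variant-count file for the two-file dialect.
#' @return A [read_count_table()] object.
#' @export
read_counts <- function(path, dialect = c("interleaved", "two-file"),
                        alt_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "interleaved") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"snv_id" %in% names(df))
      stop("malformed header: missing 'snv_id' column in ", path)
    cols <- setdiff(names(df), "snv_id")
    refc <- grep(":ref$", cols, value = TRUE)
    altc <- grep(":alt$", cols, value = TRUE)
    samples <- sub(":ref$", "", refc)
    if (length(refc) == 0L || !setequal(samples, sub(":alt$", "", altc)))
      stop("malformed header: need paired '<sample>:ref'/'<sample>:alt' columns")
    ref <- t(as.matrix(df[, paste0(samples, ":ref"), drop = FALSE]))
    alt <- t(as.matrix(df[, paste0(samples, ":alt"), drop = FALSE]))
    rownames(ref) <- rownames(alt) <- samples
    colnames(ref) <- colnames(alt) <- df$snv_id
  } else {
    if (is.null(alt_path)) stop("two-file dialect requires alt_path")
    rd <- function(p) {
      df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
      m <- t(as.matrix(df[, -1, drop = FALSE]))
      colnames(m) <- df[[1]]
      m
    }
    ref <- rd(path); alt <- rd(alt_path)
    if (!identical(dimnames(ref), dimnames(alt)))
      stop("two-file dialect: sample/SNV labels differ between files")
  }
  read_count_table(ref, alt)
}

#' Write a read-count table in the canonical interleaved dialect
#'
#' @param x A `read_counts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "read_counts"))
  df <- data.frame(snv_id = x$snv_ids, check.names = FALSE)
  for (s in x$sample_ids) {
    df[[paste0(s, ":ref")]] <- x$ref[s, ]
    df[[paste0(s, ":alt")]] <- x$alt[s, ]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale VAFs by cancer cell fraction
#'
#' Optional pre-scaling for variants affected by copy-number alteration:
#' replaces the observed VAF with CCF/2, the expected VAF of a diploid
#' heterozygous variant carried by that fraction of cancer cells. No
#' copy-number estimation is performed here; the CCF values are an input.
#'
#' @param v A samples x SNVs VAF matrix.
#' @param ccf A matrix of cancer cell fractions with the same dimnames, or a
#'   per-SNV vector recycled across samples.
#' @return The rescaled VAF matrix.
#' @export
apply_ccf <- function(v, ccf) {
  if (is.null(dim(ccf))) {
    ccf <- matrix(ccf, nrow(v), ncol(v), byrow = TRUE, dimnames = dimnames(v))
  }
  stopifnot(identical(dim(v), dim(ccf)))
  ccf / 2
}

# --- genotype encodings shared by the writers -------------------------------

genotype_to_base <- function(g) {
  b <- ifelse(is.na(g), "N", ifelse(g == 1L, "T", "A"))
  b
}

base_to_genotype <- function(b) {
  g <- ifelse(b == "N", NA_integer_, ifelse(b == "T", 1L, 0L))
  g
}

genotype_string <- function(row) {
  paste(ifelse(is.na(row), "?", row), collapse = "")
}

#' Write all outputs of a clone prediction
#'
#' Writes, under `out_dir`: `genotypes.tsv` (clones x SNVs, states 0/1/"?"),
#' `clones.fasta` (0 -> A, 1 -> T, ambiguous -> N), `frequencies.tsv`
#' (samples x clones), `tree.nwk` (Newick), and, when a migration history is
#' supplied, `migration_paths.tsv` (source, destination, support_percent,
#' status). Every file round-trips through the corresponding reader.
#'
#' @param genotypes Clones x SNVs matrix with values 0/1/NA.
#' @param frequencies Samples x clones matrix, or NULL.
#' @param tree An `ape::phylo` tree, or NULL.
#' @param history A migration-history data frame (see [infer_history()]), or
#'   NULL.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(genotypes, frequencies = NULL, tree = NULL,
                          history = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(frequencies) && ncol(frequencies) != nrow(genotypes))
    stop("dimension mismatch: ", ncol(frequencies), " frequency columns vs ",
         nrow(genotypes), " clones")
  files <- c()
  gt <- apply(genotypes, c(1, 2), function(z) if (is.na(z)) "?" else as.character(z))
  gdf <- data.frame(clone_id = rownames(genotypes), gt, check.names = FALSE)
  f <- file.path(out_dir, "genotypes.tsv")
  utils::write.table(gdf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["genotypes"] <- f

  f <- file.path(out_dir, "clones.fasta")
  seqs <- apply(genotypes, 1, function(r) paste(genotype_to_base(r), collapse = ""))
  writeLines(paste0(">", rownames(genotypes), "\n", seqs), f)
  files["fasta"] <- f

  if (!is.null(frequencies)) {
    f <- file.path(out_dir, "frequencies.tsv")
    fdf <- data.frame(sample_id = rownames(frequencies), frequencies,
                      check.names = FALSE)
    utils::write.table(fdf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["frequencies"] <- f
  }
  if (!is.null(tree)) {
    f <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, f)
    files["tree"] <- f
  }
  if (!is.null(history)) {
    f <- file.path(out_dir, "migration_paths.tsv")
    write_history(history, f)
    files["paths"] <- f
  }
  invisible(files)
}

#' Read back outputs written by [write_outputs()]
#' @param path File path.
#' @name readers
#' @return The corresponding matrix / data frame / tree.
NULL

#' @rdname readers
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  g <- matrix(suppressWarnings(as.integer(m)), nrow(m), ncol(m))
  g[m == "?"] <- NA_integer_
  dimnames(g) <- list(df$clone_id, colnames(m))
  g
}

#' @rdname readers
#' @export
read_frequencies <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname readers
#' @export
read_clone_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), "")
  g <- t(vapply(strsplit(seqs, ""), base_to_genotype,
                integer(nchar(seqs[1]))))
  rownames(g) <- ids
  colnames(g) <- paste0("snv", seq_len(ncol(g)))
  g
}

#' @rdname readers
#' @export
read_history <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  df
}

write_history <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
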