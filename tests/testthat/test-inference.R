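make_M <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("c", seq_len(nrow(m)))
  storage.mode(m) <- "integer"
  m
}

test_that("pooling removes duplicates and keeps single candidates unchanged", {
  rc <- toy_counts()
  cand1 <- make_M(c(1, 1, 0))
  cand2 <- make_M(c(1, 1, 0), c(1, 1, 1))
  M <- pool_and_filter(list(cand1, cand2), rc,
                       cb_config(qc_min_ref = 0, qc_min_alt = 0))
  expect_equal(nrow(M), 2L)
  M1 <- pool_and_filter(list(cand1), rc,
                        cb_config(qc_min_ref = 0, qc_min_alt = 0))
  expect_equal(unname(M1), unname(cand1))
})

test_that("the read-count QC filter excludes SNVs below 50 ref / 2 alt reads", {
  ref <- matrix(c(49, 30, 100, 80, 60, 55), 2, 3,
                dimnames = list(c("P", "M1"), c("a", "b", "c")))
  alt <- matrix(c(10, 12, 1, 1, 5, 0), 2, 3,
                dimnames = list(c("P", "M1"), c("a", "b", "c")))
  rc <- read_count_table(ref, alt)
  qc <- qc_pass(rc, cb_config())
  # a: max ref 49 < 50; b: alt never >= 2; c: 60 ref & 5 alt in P
  expect_equal(unname(qc), c(FALSE, FALSE, TRUE))

  # candidates identical on QC-passing SNVs collapse to one
  cands <- list(make_M(c(1, 0, 1), c(0, 1, 1), c(0, 0, 1)))
  colnames(cands[[1]]) <- c("a", "b", "c")
  M <- pool_and_filter(cands, rc, cb_config())
  expect_equal(nrow(M), 1L)
})

test_that("neighbor joining on Hamming distances recovers the caterpillar", {
  M <- make_M(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  tr <- build_tree(M)
  clades <- tree_clades(tr)
  expect_true(any(vapply(clades, identical, TRUE, y = c("c2", "c3"))))
  expect_true(any(vapply(clades, identical, TRUE, y = c("c1", "c2", "c3"))))
})

test_that("two clones give a cherry rooted at the germline", {
  M <- make_M(c(1, 0), c(0, 1))
  tr <- build_tree(M)
  expect_setequal(tr$tip.label, c("c1", "c2", "germline"))
  expect_true(any(vapply(tree_clades(tr), identical, TRUE, y = c("c1", "c2"))))
})

test_that("tree topology is invariant to clone input order", {
  M <- make_M(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0), c(1, 0, 0, 1))
  t1 <- build_tree(M)
  t2 <- build_tree(M[c(3, 1, 4, 2), ])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("identical genotype rows are rejected by tree building", {
  M <- make_M(c(1, 0), c(1, 0))
  expect_error(build_tree(M), "identical genotype rows")
})

test_that("parsimony proposes the missing shared ancestor", {
  M <- make_M(c(1, 1, 0), c(1, 0, 1))
  tr <- build_tree(M)
  M2 <- infer_ancestral_clones(tr, M)
  keys <- apply(M2, 1, paste, collapse = "")
  expect_true("100" %in% keys)
  # already-present ancestors are not re-added
  M3 <- infer_ancestral_clones(build_tree(M2), M2)
  expect_equal(nrow(M3), nrow(M2))
})

test_that("identical-prefix clones share a single added ancestor", {
  M <- make_M(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0), c(1, 1, 0, 0, 1))
  tr <- build_tree(M)
  M2 <- infer_ancestral_clones(tr, M)
  keys <- apply(M2, 1, paste, collapse = "")
  expect_equal(sum(keys == "11000"), 1L)
})

test_that("frequency regression solves the hand-worked 2x2 system", {
  M <- make_M(c(1, 0), c(1, 1))
  V <- matrix(c(0.5, 0.3), 1, 2, dimnames = list("P", c("s1", "s2")))
  f <- estimate_frequencies(M, V)
  expect_equal(unname(f[1, ]), c(0.4, 0.6), tolerance = 1e-8)
})

test_that("zero VAFs give zero frequencies", {
  M <- make_M(c(1, 0), c(1, 1))
  V <- matrix(0, 1, 2, dimnames = list("P", c("s1", "s2")))
  f <- estimate_frequencies(M, V)
  expect_equal(unname(f[1, ]), c(0, 0))
})

test_that("noise-free full-rank instances are recovered exactly", {
  set.seed(31)
  for (r in 1:20) {
    nc <- sample(2:5, 1); ns <- sample(nc:12, 1)
    repeat {
      M <- matrix(rbinom(nc * ns, 1, 0.5), nc, ns)
      if (qr(M)$rank == nc && !anyDuplicated(apply(M, 1, paste, collapse = "")))
        break
    }
    rownames(M) <- paste0("c", 1:nc); colnames(M) <- paste0("s", 1:ns)
    w <- rgamma(nc, 1); f_true <- w / sum(w)
    V <- matrix(0.5 * as.vector(f_true %*% M), 1, ns,
                dimnames = list("P", colnames(M)))
    f <- estimate_frequencies(M, V)
    expect_lt(max(abs(f[1, ] - f_true)), 1e-6)
  }
})

test_that("frequency constraints hold: nonnegative and per-sample sum <= 1", {
  set.seed(8)
  for (r in 1:10) {
    nc <- sample(3:8, 1); ns <- 20
    M <- matrix(rbinom(nc * ns, 1, 0.5), nc, ns,
                dimnames = list(paste0("c", 1:nc), paste0("s", 1:ns)))
    M <- M[!duplicated(apply(M, 1, paste, collapse = "")), , drop = FALSE]
    V <- matrix(runif(3 * ns, 0, 0.6), 3, ns,
                dimnames = list(c("A", "B", "C"), paste0("s", 1:ns)))
    f <- suppressWarnings(estimate_frequencies(M, V))
    expect_true(all(f >= 0))
    expect_true(all(rowSums(f) <= 1 + 1e-6))
  }
})

test_that("the active-set NNLS agrees with an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(13)
  for (r in 1:15) {
    m <- sample(5:15, 1); n <- sample(2:5, 1)
    A <- matrix(runif(m * n), m, n)
    b <- runif(m)
    x1 <- cloneboot:::nnls_solve(A, b)
    x2 <- pracma::lsqnonneg(A, b)$x
    expect_equal(x1, x2, tolerance = 1e-6)
  }
})

test_that("pruning follows the strict below-threshold rule", {
  M <- make_M(c(1, 0), c(1, 1), c(0, 1))
  f <- matrix(c(0.005, 0.5, 0.01,
                0.004, 0.6, 0.02), 2, 3, byrow = TRUE,
              dimnames = list(c("P", "M1"), rownames(M)))
  V <- 0.5 * f %*% M
  pr <- prune_low_frequency(M, f, V, threshold = 0.01)
  # clone 1 max 0.005 < 0.01 -> removed; clone 3 at exactly 0.01 -> kept
  expect_false("c1" %in% rownames(pr$M))
  expect_true(all(c("c2", "c3") %in% rownames(pr$M)))

  pr2 <- prune_low_frequency(pr$M, pr$f, V, threshold = 0.01)
  expect_equal(rownames(pr2$M), rownames(pr$M))
})

test_that("pruning everything falls back to the best single clone", {
  M <- make_M(c(1, 1))
  f <- matrix(0.004, 1, 1, dimnames = list("P", "c1"))
  V <- matrix(c(0.002, 0.002), 1, 2, dimnames = list("P", c("s1", "s2")))
  expect_warning(pr <- prune_low_frequency(M, f, V, 0.01), "keeping")
  expect_equal(nrow(pr$M), 1L)
})

test_that("hybrid decomposition is a no-op at an exact model fit", {
  M <- make_M(c(1, 1, 0, 0), c(1, 1, 1, 1))
  f <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("P", rownames(M)))
  V <- 0.5 * f %*% M
  M2 <- decompose_hybrids(M, V, f, threshold = 0.01)
  expect_identical(M2, M)
})

test_that("hybrid decomposition recovers two merged clones", {
  # truth: X = {s1,s2}, Y = {s1,s3}; the candidate pool holds the shared
  # ancestor {s1} plus the merged clone {s1,s2,s3}
  Mt <- make_M(c(1, 1, 0), c(1, 0, 1))
  ft <- matrix(c(0.6, 0.4,
                 0.2, 0.8), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), rownames(Mt)))
  V <- 0.5 * ft %*% Mt
  M <- make_M(c(1, 0, 0), c(1, 1, 1))
  f <- estimate_frequencies(M, V)
  M2 <- suppressWarnings(decompose_hybrids(M, V, f, threshold = 0.01))
  keys <- apply(M2, 1, paste, collapse = "")
  expect_true(all(c("110", "101") %in% keys))
})

test_that("finalize assigns unassigned SNVs by VAF-profile proximity", {
  M <- make_M(c(1, 0, 0), c(1, 1, 0))
  f <- matrix(c(0.3, 0.6), 1, 2, dimnames = list("P", rownames(M)))
  V <- matrix(c(0.45, 0.30, 0.31), 1, 3,
              dimnames = list("P", paste0("s", 1:3)))
  pred <- finalize_prediction(M, f, V)
  # s3 VAF 0.31 ~ expected 0.30 of clone c2 (f = 0.6)
  expect_equal(pred$genotypes["c2", "s3"], 1L)
  expect_equal(pred$genotypes["c1", "s3"], 0L)

  # exact tie between the clones -> higher mean frequency wins
  f2 <- matrix(c(0.8, 0.4), 1, 2, dimnames = list("P", rownames(M)))
  V2 <- matrix(c(0.40, 0.20, 0.30), 1, 3,
               dimnames = list("P", paste0("s", 1:3)))
  pred2 <- finalize_prediction(M, f2, V2)
  expect_equal(pred2$genotypes["c1", "s3"], 1L)
  expect_equal(pred2$genotypes["c2", "s3"], 0L)
})

test_that("no-op finalization leaves genotypes unchanged", {
  M <- make_M(c(1, 0), c(1, 1))
  f <- matrix(c(0.4, 0.6), 1, 2, dimnames = list("P", rownames(M)))
  V <- 0.5 * f %*% M
  pred <- finalize_prediction(M, f, V)
  expect_equal(pred$genotypes[, colnames(M)], M)
})

test_that("the full engine recovers clearly separated clones at high depth", {
  truth <- simulate_truth(n_clones = 3, n_snvs = 15, n_samples = 3, seed = 21)
  rc <- simulate_reads(truth, depth_mean = 1000, depth_dispersion = 50,
                       seed = 22)
  pred <- suppressWarnings(run_clonefinder_plus(rc))
  ge <- genotype_error(truth$genotypes, pred$genotypes)
  expect_equal(ge$dataset_ge, 0)
})

test_that("a monoclonal sample yields one clone at twice the mean VAF", {
  ref <- matrix(rep(60L, 8), 2, 4,
                dimnames = list(c("P", "M1"), paste0("s", 1:4)))
  alt <- matrix(rep(40L, 8), 2, 4, dimnames = dimnames(ref))
  rc <- read_count_table(ref, alt)
  pred <- suppressWarnings(run_clonefinder_plus(rc))
  expect_equal(nrow(pred$genotypes), 1L)
  expect_equal(unname(pred$genotypes[1, ]), rep(1L, 4))
  expect_equal(unname(pred$frequencies[, 1]), c(0.8, 0.8), tolerance = 1e-6)
})

test_that("the engine handles the simulated dataset size range", {
  for (case in list(c(6, 9, 5), c(26, 99, 8))) {
    truth <- simulate_truth(case[1], case[2], case[3], seed = 31 + case[1])
    rc <- simulate_reads(truth, depth_mean = 100, seed = 32 + case[1])
    pred <- suppressWarnings(run_clonefinder_plus(rc))
    expect_s3_class(pred, "clone_prediction")
    expect_true(all(colSums(pred$genotypes) >= 1L))
    expect_true(all(pred$frequencies >= 0))
    expect_true(all(rowSums(pred$frequencies) <= 1 + 1e-6))
  }
})

test_that("the engine is deterministic for a fixed input", {
  truth <- simulate_truth(5, 20, 3, seed = 77)
  rc <- simulate_reads(truth, depth_mean = 100, seed = 78)
  p1 <- suppressWarnings(run_clonefinder_plus(rc))
  p2 <- suppressWarnings(run_clonefinder_plus(rc))
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$frequencies, p2$frequencies)
})

test_that("accepted clone additions never worsen the regression fit", {
  set.seed(55)
  truth <- simulate_truth(6, 24, 4, seed = 41)
  rc <- simulate_reads(truth, depth_mean = 200, seed = 42)
  V <- vaf(rc)
  chains <- lapply(rc$sample_ids, function(s)
    cluster_sample(rc$alt[s, ], rc$ref[s, ], sample_id = s))
  cands <- lapply(chains, candidates_from_chain, all_snv_ids = rc$snv_ids)
  M <- pool_and_filter(cands, rc)
  f <- estimate_frequencies(M, V)
  r0 <- cloneboot:::fit_residual(M, f, V)
  M2 <- infer_ancestral_clones(build_tree(M), M)
  f2 <- estimate_frequencies(M2, V)
  r1 <- cloneboot:::fit_residual(M2, f2, V)
  expect_lte(r1, r0 + 1e-9)
  M3 <- suppressWarnings(decompose_hybrids(M2, V, f2, 0.01))
  f3 <- suppressWarnings(estimate_frequencies(M3, V))
  r2 <- cloneboot:::fit_residual(M3, f3, V)
  expect_lte(r2, r1 + 1e-9)
})
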