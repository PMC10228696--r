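test_that("clones confined to the primary site imply no migration", {
  M <- rbind(c1 = c(1L, 0L), c2 = c(1L, 1L))
  colnames(M) <- c("s1", "s2")
  tr <- build_tree(M)
  h <- infer_history(tr, list(c1 = "P", c2 = "P"), "P")
  expect_equal(nrow(h$paths), 0L)
})

test_that("a metastatic cherry under a primary root yields a single path", {
  M <- rbind(c1 = c(1L, 0L), c2 = c(1L, 1L))
  colnames(M) <- c("s1", "s2")
  tr <- build_tree(M)
  h <- infer_history(tr, list(c1 = "P", c2 = "liver"), "P")
  expect_equal(nrow(h$paths), 1L)
  expect_equal(h$paths$source, "P")
  expect_equal(h$paths$destination, "liver")
})

test_that("a clone shared by two sites emits a zero-mutation co-location path", {
  M <- rbind(c1 = c(1L, 0L), c2 = c(1L, 1L))
  colnames(M) <- c("s1", "s2")
  tr <- build_tree(M)
  h <- infer_history(tr, list(c1 = "P", c2 = c("GEJ", "heart")), "P")
  keys <- paste(h$paths$source, h$paths$destination)
  expect_length(keys, 2L)
  ann <- map_mutations_to_paths(tr, M, h)
  inter <- ann[ann$source != "P", ]
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$n_mutations, 0L)
  expect_true(is.na(inter$driver_rate))
})

test_that("Sankoff labeling attains the brute-force minimum migration count", {
  set.seed(7)
  for (r in 1:25) {
    nc <- sample(3:6, 1)
    ns <- sample(2:4, 1)
    truth <- simulate_truth(nc, nc + 5, min(ns, nc), seed = r)
    h <- infer_history(truth$tree, as.list(truth$clone_sites), "P")
    leaf_sites <- c(truth$clone_sites, germline = "P")
    expect_equal(nrow(h$paths),
                 brute_force_migrations(truth$tree, leaf_sites, "P"))
  }
})

test_that("branch mutations and drivers annotate the emitting path", {
  # germline - c1 {s1,s2,s3} in P - c2 {+s4} in liver
  M <- rbind(c1 = c(1L, 1L, 1L, 0L), c2 = c(1L, 1L, 1L, 1L))
  colnames(M) <- paste0("s", 1:4)
  tr <- build_tree(M)
  h <- infer_history(tr, list(c1 = "P", c2 = "liver"), "P")
  drivers <- c(s1 = FALSE, s2 = FALSE, s3 = FALSE, s4 = TRUE)
  ann <- map_mutations_to_paths(tr, M, h, drivers)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$n_mutations, 1L)
  expect_equal(ann$n_drivers, 1L)
  expect_equal(ann$driver_rate, 1)

  # three mutations on the migrating branch, one a driver
  M2 <- rbind(c1 = c(1L, 0L, 0L, 0L), c2 = c(1L, 1L, 1L, 1L))
  colnames(M2) <- paste0("s", 1:4)
  tr2 <- build_tree(M2)
  h2 <- infer_history(tr2, list(c1 = "P", c2 = "liver"), "P")
  ann2 <- map_mutations_to_paths(tr2, M2, h2,
                                 c(s1 = FALSE, s2 = TRUE, s3 = FALSE,
                                   s4 = FALSE))
  expect_equal(ann2$n_mutations, 3L)
  expect_equal(ann2$n_drivers, 1L)
  expect_equal(ann2$driver_rate, 1 / 3)
})

test_that("consensus history follows the greedy support-then-reachability rule", {
  mk <- function(...) data.frame(source = c(...)[c(TRUE, FALSE)],
                                 destination = c(...)[c(FALSE, TRUE)])
  # P->A in 9/10, A->B in 5/10, P->B in 4/10
  histories <- lapply(1:10, function(r) {
    paths <- mk("P", "A")
    if (r <= 5) paths <- rbind(paths, mk("A", "B"))
    if (r > 6) paths <- rbind(paths, mk("P", "B"))
    if (r == 10) paths <- mk("P", "B")  # replicate without P->A
    paths
  })
  ch <- consensus_history(histories, primary = "P", threshold = 50)
  key <- paste(ch$source, ch$destination)
  expect_setequal(key, c("P A", "A B"))
  expect_equal(ch$status[key == "P A"], "solid")
  expect_equal(ch$status[key == "A B"], "solid")  # support exactly 50
})

test_that("sub-threshold paths are added tentatively only to restore reachability", {
  histories <- c(
    lapply(1:9, function(r) data.frame(source = "P", destination = "A")),
    list(data.frame(source = c("P", "A"), destination = c("A", "B"))))
  ch <- consensus_history(histories, primary = "P", threshold = 60)
  expect_equal(nrow(ch), 2L)
  ab <- ch[ch$destination == "B", ]
  expect_equal(ab$status, "tentative")
  expect_equal(ab$support_percent, 10)
})

test_that("identical replicate histories give a 100%-support consensus", {
  h <- data.frame(source = c("P", "A"), destination = c("A", "B"))
  ch <- consensus_history(lapply(1:30, function(r) h), "P", threshold = 60)
  expect_equal(nrow(ch), 2L)
  expect_true(all(ch$support_percent == 100))
  expect_true(all(ch$status == "solid"))
})

test_that("every observed site is reachable from the primary in a consensus", {
  set.seed(3)
  for (r in 1:10) {
    histories <- lapply(1:8, function(i) {
      n <- sample(1:4, 1)
      sites <- c("P", "A", "B", "C")
      # random connected-ish histories
      data.frame(source = sample(sites, n, replace = TRUE),
                 destination = sample(c("A", "B", "C"), n, replace = TRUE))
    })
    histories <- lapply(histories, function(h) h[h$source != h$destination, ,
                                                 drop = FALSE])
    ch <- consensus_history(histories, "P", threshold = 60)
    observed <- unique(unlist(lapply(histories, function(h)
      c(h$source, h$destination))))
    reach <- "P"
    repeat {
      nxt <- unique(ch$destination[ch$source %in% reach &
                                     !(ch$destination %in% reach)])
      if (length(nxt) == 0) break
      reach <- c(reach, nxt)
    }
    pool_reach <- "P"
    pooled <- unique(do.call(rbind, histories))
    repeat {
      nxt <- unique(pooled$destination[pooled$source %in% pool_reach &
                                         !(pooled$destination %in% pool_reach)])
      if (length(nxt) == 0) break
      pool_reach <- c(pool_reach, nxt)
    }
    # everything reachable in the pooled graph is reachable in the consensus
    expect_true(all(intersect(observed, pool_reach) %in% reach))
  }
})

test_that("the solid-path set shrinks as the threshold rises", {
  histories <- lapply(1:10, function(r) {
    paths <- data.frame(source = "P", destination = "A")
    if (r <= 7) paths <- rbind(paths, data.frame(source = "A", destination = "B"))
    if (r <= 3) paths <- rbind(paths, data.frame(source = "P", destination = "C"))
    paths
  })
  n_solid <- vapply(c(10, 40, 75, 95), function(th) {
    ch <- consensus_history(histories, "P", threshold = th)
    sum(ch$status == "solid")
  }, numeric(1))
  expect_true(all(diff(n_solid) <= 0))
})

test_that("driver-rate comparison matches the closed-form t statistic", {
  mk_ann <- function(p_rate, m_rate) {
    data.frame(source = c("P", "M1"), destination = c("M1", "M2"),
               n_mutations = c(10L, 10L),
               n_drivers = c(round(p_rate * 10), round(m_rate * 10)),
               driver_rate = c(p_rate, m_rate))
  }
  set.seed(91)
  pr <- round(rnorm(20, 0.3, 0.05), 1)
  mr <- round(rnorm(20, 0.1, 0.05), 1)
  anns <- lapply(1:20, function(i) mk_ann(pr[i], mr[i]))
  res <- compare_driver_rates(anns, "P")
  x <- round(pr * 10) / 10; y <- round(mr * 10) / 10
  tt <- (mean(x) - mean(y)) / sqrt(var(x) / 20 + var(y) / 20)
  expect_equal(res$rate_test$t, tt, tolerance = 1e-10)
  expect_lt(res$rate_test$p_value, 0.01)
})

test_that("degenerate variance cases are reported, not crashed", {
  mk_ann <- function(p_rate, m_rate)
    data.frame(source = c("P", "M1"), destination = c("M1", "M2"),
               n_mutations = c(10L, 10L), n_drivers = c(p_rate, m_rate) * 10,
               driver_rate = c(p_rate, m_rate))
  same <- lapply(1:30, function(i) mk_ann(0.1, 0.1))
  res <- compare_driver_rates(same, "P")
  expect_equal(res$rate_test$t, 0)
  expect_equal(res$rate_test$p_value, 1)

  diff <- lapply(1:30, function(i) mk_ann(0.1, 0))
  # both the count and the rate comparison warn about zero variance
  expect_warning(expect_warning(res2 <- compare_driver_rates(diff, "P"),
                                "zero variance"), "zero variance")
  expect_true(is.infinite(res2$rate_test$t))
  expect_equal(res2$rate_test$p_value, 0)
})
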