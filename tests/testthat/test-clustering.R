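## two populations with disjoint expressed gene sets
separable_nm <- function(n1 = 60, n2 = 60, seed = 1) {
  set.seed(seed)
  X <- matrix(0, 20, n1 + n2,
              dimnames = list(paste0("g", 1:20),
                              paste0("c", seq_len(n1 + n2))))
  X[1:10, 1:n1] <- rpois(10 * n1, 8)
  X[11:20, (n1 + 1):(n1 + n2)] <- rpois(10 * n2, 8)
  X[1, ] <- X[1, ] + 1  # keep column totals positive
  log_normalize(Matrix::Matrix(X, sparse = TRUE))
}

test_that("disjoint populations separate into two pure clusters", {
  nm <- separable_nm()
  emb <- reduce_and_cluster(nm, n_variable = 20, n_dims = 5,
                            resolution = 0.5, seed = 1)
  expect_identical(nlevels(emb$cluster), 2L)
  truth <- rep(c("p1", "p2"), c(60, 60))
  purity <- max(table(emb$cluster[truth == "p1"])) +
            max(table(emb$cluster[truth == "p2"]))
  expect_identical(as.integer(purity), 120L)
  expect_true(all(is.finite(emb$x)) && all(is.finite(emb$y)))
})

test_that("cluster count is non-decreasing in resolution on a fixed fixture", {
  f <- axis_fixture(7)
  nm <- f$nm[, 1:800]
  counts <- vapply(c(0.1, 0.5, 1.0, 2.5, 3.3), function(res) {
    emb <- reduce_and_cluster(nm, n_variable = 200, n_dims = 20,
                              resolution = res, seed = 1, umap = FALSE)
    nlevels(emb$cluster)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
})

test_that("clustering and embedding are deterministic given the seed", {
  nm <- separable_nm(40, 40)
  e1 <- reduce_and_cluster(nm, n_variable = 20, n_dims = 5,
                           resolution = 0.8, seed = 9)
  e2 <- reduce_and_cluster(nm, n_variable = 20, n_dims = 5,
                           resolution = 0.8, seed = 9)
  expect_identical(e1$cluster, e2$cluster)
  expect_identical(e1$x, e2$x)
  expect_error(reduce_and_cluster(nm, n_dims = 1000, resolution = 1),
               "n_dims")
})

test_that("markers obey the strict detection-fraction and alpha thresholds", {
  f <- marker_fixture()
  mk <- find_cluster_markers(f$nm, f$emb)
  a_mk <- mk[mk$cluster == "A", ]
  expect_true("g1" %in% a_mk$gene_id)       # 100% in / 0% out
  expect_lt(a_mk$adjusted_p[a_mk$gene_id == "g1"], 1e-10)
  expect_false("g2" %in% a_mk$gene_id)      # pct_in exactly 0.25 is excluded
  ## with alpha out of the way, the strict pct rule alone excludes g2 ...
  strict <- find_cluster_markers(f$nm, f$emb, min_pct_in = 0.25, alpha = 0.5)
  expect_false("g2" %in% strict$gene_id[strict$cluster == "A"])
  ## ... and relaxing the thresholds admits it (monotonicity of the filter)
  mk2 <- find_cluster_markers(f$nm, f$emb, min_pct_in = 0.2, alpha = 0.5)
  expect_true("g2" %in% mk2$gene_id[mk2$cluster == "A"])
  expect_true(all(mk$gene_id %in% mk2$gene_id))
})

test_that("permuting cluster labels yields essentially no markers", {
  f <- marker_fixture()
  set.seed(11)
  total <- 0
  for (i in 1:20) {
    emb <- f$emb
    emb$cluster <- sample(emb$cluster)
    total <- total + nrow(find_cluster_markers(f$nm, emb))
  }
  expect_lte(total, 2)
})

test_that("pseudocluster diagnosis flags halved-depth clusters only", {
  set.seed(2)
  X <- matrix(rpois(50 * 90, 5), 50,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:90)))
  X[, 61:90] <- matrix(rpois(50 * 30, 1), 50)  # low-depth cluster
  m <- Matrix::Matrix(X, sparse = TRUE)
  emb <- data.frame(nucleus_id = colnames(X), x = 0, y = 0,
                    cluster = rep(c("a", "b", "low"), each = 30),
                    stringsAsFactors = FALSE)
  fl <- diagnose_low_quality_clusters(m, emb)
  expect_identical(fl$cluster[fl$flagged], "low")
  expect_false(any(diagnose_low_quality_clusters(m, emb, fraction = 0)$flagged))
  emb$cluster <- rep(c("a", "b", "c"), 30)  # homogeneous mixture
  expect_false(any(diagnose_low_quality_clusters(m, emb)$flagged))
})

test_that("nucleus subsampling is exact, exhaustive at n = total, and seeded", {
  m <- Matrix::Matrix(matrix(rpois(10 * 200, 2), 10), sparse = TRUE)
  dimnames(m) <- list(paste0("g", 1:10), paste0("b", 1:200))
  subs <- subsample_nuclei(m, 50, trials = 10, seed = 4)
  expect_length(subs, 10)
  for (s in subs) expect_identical(length(unique(colnames(s))), 50L)
  subs2 <- subsample_nuclei(m, 50, trials = 10, seed = 4)
  expect_identical(lapply(subs, colnames), lapply(subs2, colnames))
  full <- subsample_nuclei(m, 200, trials = 1, seed = 1)[[1]]
  expect_setequal(colnames(full), colnames(m))
  expect_error(subsample_nuclei(m, 201, 1, 1), "exceeds")
})
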