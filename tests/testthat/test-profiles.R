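## a hand-built position table on a straight axis with termini (2, 12)
toy_positions <- function(n = 400, a = 2, b = 12, seed = 1) {
  set.seed(seed)
  pos <- data.frame(nucleus_id = paste0("n", seq_len(n)),
                    position = seq(a, b, length.out = n),
                    distance = runif(n, 0, 0.2), stringsAsFactors = FALSE)
  attr(pos, "terminus") <- c(anterior = a, posterior = b)
  pos
}

test_that("near-axis selection is inclusive at the threshold", {
  pos <- toy_positions(5)
  pos$distance <- c(0, 0.1, 0.3, 0.300001, 2)
  kept <- select_near_axis(pos, 0.3)
  expect_identical(kept$nucleus_id, c("n1", "n2", "n3"))
  expect_identical(nrow(select_near_axis(pos, Inf)), 5L)
  expect_identical(select_near_axis(pos, 0)$nucleus_id, "n1")
})

test_that("mirroring doubles the table, fixes the termini and preserves symmetry", {
  pos <- toy_positions(100)
  dbl <- mirror_positions(pos)
  expect_identical(nrow(dbl), 200L)
  ## nucleus at the anterior terminus mirrors onto itself
  expect_equal(dbl$position[101], pos$position[1])
  ## mirrored range is [2a - c, 2b - c]
  a <- 2; b <- 12; cc <- 7
  expect_gte(min(dbl$position), 2 * a - cc)
  expect_lte(max(dbl$position), 2 * b - cc)
  ## a multiset symmetric about c stays symmetric
  pos2 <- toy_positions(50)
  pos2$position <- c(seq(3, 6, length.out = 25), 14 - seq(3, 6, length.out = 25))
  dbl2 <- mirror_positions(pos2)
  expect_equal(sort(dbl2$position), sort(14 - dbl2$position), tolerance = 1e-9)
})

test_that("loess smoothing reproduces constants and noiseless lines", {
  pos <- toy_positions(600)
  dbl <- mirror_positions(pos)
  prm <- smoothing_params(span = 0.1)
  const <- smooth_profile(dbl, rep(3.7, nrow(dbl)), prm)
  expect_length(const, 80)
  expect_equal(const, rep(3.7, 80), tolerance = 1e-8)

  vals <- 2 * dbl$position + 1
  lin <- smooth_profile(dbl, vals, prm)
  grid_kept <- seq(2 - 5, 12 + 5, length.out = 160)[41:120]
  expect_lt(max(abs(lin - (2 * grid_kept + 1))) / diff(range(vals)), 0.01)
  expect_error(smooth_profile(dbl[dbl$position == dbl$position[1], ],
                              rep(1, 2), prm), "points|degenerate")
})

test_that("mirrored smoothing of an even function has zero terminal slope", {
  pos <- toy_positions(800)
  dbl <- mirror_positions(pos)
  vals <- (dbl$position - 2)^2          # even about the anterior terminus
  prof <- smooth_profile(dbl, vals, smoothing_params(span = 0.1))
  d <- first_derivative(prof)
  expect_lt(abs(d[1]), 0.05 * max(abs(d)))
})

test_that("profile matrix covers all genes, zeroes empty genes and ignores order", {
  f <- fx("prof_toy", {
    set.seed(8)
    n <- 300
    pos <- toy_positions(n)
    X <- matrix(rpois(5 * n, 3), 5, n,
                dimnames = list(paste0("g", 1:5), pos$nucleus_id))
    X[5, ] <- 0
    X[1, ] <- X[1, ] + 1
    nm <- log_normalize(Matrix::Matrix(X, sparse = TRUE))
    list(nm = nm, pos = pos)
  })
  prm <- smoothing_params(near_axis_threshold = 0.3, span = 0.2)
  prof <- build_profile_matrix(f$nm, f$pos, prm)
  expect_identical(dim(prof), c(5L, 80L))
  expect_identical(unname(prof["g5", ]), rep(0, 80))
  ## nucleus order invariance
  perm <- sample(nrow(f$pos))
  pos2 <- f$pos[perm, ]
  attr(pos2, "terminus") <- attr(f$pos, "terminus")
  prof2 <- build_profile_matrix(f$nm, pos2, prm)
  expect_equal(prof2, prof, tolerance = 1e-10)
  expect_error(build_profile_matrix(f$nm, within(f$pos, nucleus_id <- paste0("x", nucleus_id)), prm),
               "IDs")
})

test_that("profiles separate a noiseless bi-split gene into its two peaks", {
  panel <- list(
    stripe_spec("bi", "bi_split", peak_centers = c(0.15, 0.25),
                dispersion = Inf, amplitude = 20),
    stripe_spec("hk", "uniform", baseline = 20))
  sim <- simulate_embryo(4000, 0, panel, seed = 1, lib_size_sdlog = 0)
  emb <- embed_ground_truth(sim$truth, "line", noise_sd = 0, seed = 1)
  curve <- fit_axis_curve(cbind(seq(0, 10, length.out = 8), 0))
  pos <- assign_positions(emb, curve, unique(emb$cluster))
  nm <- log_normalize(sim$counts)
  prof <- build_profile_matrix(nm, pos, smoothing_params())
  p <- prof["bi", ]
  peaks <- which(diff(sign(diff(p))) == -2) + 1
  peaks <- peaks[p[peaks] > 0.2 * max(p)]
  expect_length(peaks, 2)
  expect_lte(abs(peaks[1] - 0.15 * 80), 2)
  expect_lte(abs(peaks[2] - 0.25 * 80), 2)
})
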