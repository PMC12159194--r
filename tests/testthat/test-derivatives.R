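test_that("first derivative uses central differences with one-sided terminals", {
  x <- 2 * (1:80)
  expect_equal(first_derivative(x), rep(2, 80))
  expect_equal(first_derivative(c(1, 2, 4))[2], 1.5)
  expect_error(first_derivative(c(1, NA, 3)), "finite")
  ## matrix dispatch preserves shape and names
  M <- rbind(a = 1:80, b = (1:80)^2)
  D <- first_derivative(M)
  expect_identical(dimnames(D), dimnames(M))
  expect_equal(D["a", ], rep(1, 80), ignore_attr = TRUE)
})

test_that("interior derivatives satisfy the telescoping identity on random profiles", {
  set.seed(6)
  for (i in 1:50) {
    x <- rnorm(80)
    d <- first_derivative(x)
    expect_equal(sum(d[2:79]), (x[80] + x[79] - x[1] - x[2]) / 2,
                 tolerance = 1e-12)
  }
})

test_that("reversing a profile negates and reverses the interior derivative", {
  set.seed(7)
  x <- cumsum(rnorm(80))
  d <- first_derivative(x)
  dr <- first_derivative(rev(x))
  expect_equal(dr[2:79], -rev(d[2:79]), tolerance = 1e-12)
})

test_that("extreme tables rank deterministically and catch planted steps", {
  set.seed(8)
  D <- matrix(0, 5, 80, dimnames = list(paste0("g", 1:5), NULL))
  D["g3", 40] <- 10
  D["g2", 40] <- -10
  tab <- top_extremes_table(D, k = 2)
  at40 <- tab[tab$position == 40, ]
  expect_identical(at40$gene_id[at40$side == "high" & at40$rank == 1], "g3")
  expect_identical(at40$gene_id[at40$side == "low" & at40$rank == 1], "g2")
  ## ties broken by gene id
  expect_identical(at40$gene_id[at40$side == "high" & at40$rank == 2], "g1")
  full <- top_extremes_table(D, k = 5)
  expect_setequal(full$gene_id[full$position == 1], rownames(D))
  expect_error(top_extremes_table(D, k = 6), "gene count")
})

test_that("position correlation maps are symmetric with unit diagonal", {
  set.seed(9)
  D <- matrix(rnorm(20 * 80), 20, dimnames = list(paste0("g", 1:20), NULL))
  D[, 50] <- D[, 10]                      # identical positions
  pc <- position_correlation(D)
  expect_equal(pc[10, 50], 1)
  expect_equal(pc, t(pc))
  expect_equal(unname(diag(pc)), rep(1, 80))
  expect_true(all(abs(pc) <= 1 + 1e-12))
  D0 <- D; D0[, 3] <- 0                   # zero variance -> missing
  expect_true(all(is.na(position_correlation(D0)[3, -3])))
  expect_error(position_correlation(D, genes = paste0("g", 1:2)), ">= 3")
})

test_that("region grouping respects the strict 0.2 filter and separates antiphase cohorts", {
  idx <- 1:80
  mk <- function(phase, amp = 1) amp * sin(2 * pi * (idx - phase) / 12)
  prof <- rbind(
    a1 = pmax(mk(0), 0) + 0.3, a2 = pmax(mk(0.5), 0) + 0.3,
    a3 = pmax(mk(1), 0) + 0.3,
    b1 = pmax(mk(6), 0) + 0.3, b2 = pmax(mk(6.5), 0) + 0.3,
    b3 = pmax(mk(7), 0) + 0.3,
    weak = rep(0.2, 80),                  # region max exactly 0.2 -> retained
    off = rep(0.1, 80))                   # below 0.2 -> excluded
  prof["weak", 60] <- 0.2
  der <- first_derivative(prof)
  expect_warning(gr <- region_gene_groups(prof, der, region = c(55, 80),
                                          n_groups = 3),
                 "zero derivative variance")
  expect_false("off" %in% names(gr))
  ## antiphase cohorts split cleanly at a 2-group cut
  gr2 <- region_gene_groups(prof[1:6, ], der[1:6, ], region = c(55, 80),
                            n_groups = 2)
  expect_length(unique(gr2[c("a1", "a2", "a3")]), 1)
  expect_length(unique(gr2[c("b1", "b2", "b3")]), 1)
  expect_false(gr2["a1"] == gr2["b1"])
  ## singleton cut
  gr3 <- region_gene_groups(prof[1:6, ], der[1:6, ], region = c(55, 80),
                            n_groups = 6)
  expect_length(unique(gr3), 6)
  expect_error(region_gene_groups(prof, der, region = c(80, 55), n_groups = 2),
               "region")
})

test_that("gene-pair networks apply strict expression and correlation thresholds", {
  n <- 20
  pos <- data.frame(nucleus_id = paste0("n", 1:n),
                    position = seq(0, 10, length.out = n), distance = 0,
                    stringsAsFactors = FALSE)
  attr(pos, "terminus") <- c(anterior = 0, posterior = 10)
  set.seed(10)
  X <- matrix(rpois(6 * n, 4) + 1, 6, n,
              dimnames = list(paste0("g", 1:6), pos$nucleus_id))
  X[2, ] <- X[1, ]                         # identical pair -> r = 1
  X[3, ] <- 0; X[3, 1:2] <- 5              # expressed in exactly 10%
  X[4, ] <- 0; X[4, 1:3] <- 5              # 15%, retained
  nm <- Matrix::Matrix(X, sparse = TRUE)   # treat as normalized values
  edges <- gene_pair_network(nm, pos, window = c(1, 80),
                             genes = rownames(X), min_expr_frac = 0.10,
                             r_threshold = 0.5)
  pair <- edges[edges$gene_a == "g1" & edges$gene_b == "g2", ]
  expect_identical(nrow(pair), 1L)
  expect_equal(pair$r, 1)
  expect_identical(pair$sign, "positive")
  expect_false(any(edges$gene_a == "g3" | edges$gene_b == "g3"))

  ## antiphase expression in a window yields a negative edge; a window across
  ## a phase change changes the edge set
  m2 <- rbind(o1 = c(5, 4, 5, 4, 0, 1, 0, 1, 5, 0, 5, 1, 4, 1, 5, 1, 3, 2, 4, 1),
              o2 = c(0, 1, 0, 1, 5, 4, 5, 4, 1, 5, 0, 4, 1, 5, 0, 5, 2, 3, 1, 4))
  colnames(m2) <- pos$nucleus_id
  nm2 <- Matrix::Matrix(m2, sparse = TRUE)
  e1 <- gene_pair_network(nm2, pos, window = c(1, 40), genes = rownames(m2))
  expect_identical(e1$sign, "negative")
  expect_lt(e1$r, -0.5)
  expect_error(gene_pair_network(nm2, pos, window = c(1, 10),
                                 genes = rownames(m2)), "10 nuclei")
})
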