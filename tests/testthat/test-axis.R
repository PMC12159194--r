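test_that("manual control points pass through verbatim", {
  mp <- cbind(c(0, 1, 2, 3.5), c(0, 0.5, 0.2, 1))
  emb <- data.frame(nucleus_id = "n1", x = 0, y = 0, cluster = "c")
  r <- extract_ridge_control_points(emb, "c", manual_points = mp)
  expect_identical(r$control_points, mp)
  expect_identical(r$anterior_anchor, mp[1, ])
  expect_identical(r$posterior_anchor, mp[4, ])
})

test_that("collinear control points give positions equal to Euclidean distance", {
  cp <- cbind(seq(0, 8, by = 1), 0)
  curve <- fit_axis_curve(cp, n_polyline = 5000)
  emb <- data.frame(nucleus_id = c("a", "b", "c"),
                    x = c(0, 3, 8), y = c(0, 0.4, 0), cluster = "k",
                    stringsAsFactors = FALSE)
  pos <- assign_positions(emb, curve, "k")
  expect_lt(max(abs(pos$position - curve$terminus[1] - c(0, 3, 8))), 5e-3)
  expect_lt(max(abs(pos$distance - c(0, 0.4, 0))), 5e-3)
})

test_that("semicircle arc length is pi within 0.5% and the polyline has the requested size", {
  th <- seq(0, pi, length.out = 15)
  cp <- cbind(cos(th), sin(th))
  curve <- fit_axis_curve(cp, n_polyline = 10000)
  expect_identical(nrow(curve$polyline), 10000L)
  expect_identical(length(curve$position), 10000L)
  expect_lt(abs(diff(curve$terminus) - pi) / pi, 0.005)
  ## uniform spacing within 1% relative tolerance
  sp <- sqrt(rowSums(diff(curve$polyline)^2))
  expect_lt(max(abs(sp - mean(sp))) / mean(sp), 0.01)
  ## strictly increasing arc positions, anterior before posterior
  expect_true(all(diff(curve$position) > 0))
  expect_lt(curve$terminus[1], curve$terminus[2])
  expect_error(fit_axis_curve(cp[1:3, ]), ">= 4")
})

test_that("accelerated nearest-point search matches the brute-force oracle", {
  f <- axis_fixture(7)
  poly <- f$curve$polyline
  set.seed(1)
  pts <- cbind(runif(120, min(poly[, 1]), max(poly[, 1])),
               runif(120, min(poly[, 2]), max(poly[, 2])))
  fast <- nearest_point_index(pts, poly, chunk = 37)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (poly[, 1] - pts[i, 1])^2 + (poly[, 2] - pts[i, 2])^2
    which.min(d2)  # lowest index on ties
  }, 0L)
  expect_identical(fast, oracle)
})

test_that("nuclei beyond the termini are omitted via extension membership", {
  cp <- cbind(0:7, 0)
  curve <- fit_axis_curve(cp, n_polyline = 4000)
  emb <- data.frame(nucleus_id = c("in", "past_p", "past_a"),
                    x = c(4, 7.5, -0.4), y = 0, cluster = "k",
                    stringsAsFactors = FALSE)
  pos <- assign_positions(emb, curve, "k")
  expect_identical(pos$nucleus_id, "in")
  ## a nucleus coincident with a polyline point has distance exactly 0
  k <- 1500
  emb2 <- data.frame(nucleus_id = "hit", x = curve$polyline[k, 1],
                     y = curve$polyline[k, 2], cluster = "k",
                     stringsAsFactors = FALSE)
  p2 <- assign_positions(emb2, curve, "k")
  expect_identical(p2$distance, 0)
  expect_identical(p2$position, curve$position[k])
})

test_that("positions and distances are invariant under rigid motions", {
  set.seed(3)
  cp <- cbind(seq(0, 5, length.out = 8), sin(seq(0, 5, length.out = 8)))
  nuc <- cbind(runif(50, 0, 5), runif(50, -1, 2))
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(11, -4)
  emb1 <- data.frame(nucleus_id = paste0("n", 1:50), x = nuc[, 1],
                     y = nuc[, 2], cluster = "k", stringsAsFactors = FALSE)
  nuc2 <- sweep(nuc %*% t(R), 2, shift, "+")
  emb2 <- emb1; emb2$x <- nuc2[, 1]; emb2$y <- nuc2[, 2]
  c1 <- fit_axis_curve(cp, n_polyline = 5000)
  c2 <- fit_axis_curve(sweep(cp %*% t(R), 2, shift, "+"), n_polyline = 5000)
  p1 <- assign_positions(emb1, c1, "k")
  p2 <- assign_positions(emb2, c2, "k")
  expect_identical(p1$nucleus_id, p2$nucleus_id)
  expect_equal(p1$position, p2$position, tolerance = 1e-8)
  expect_equal(p1$distance, p2$distance, tolerance = 1e-8)
})

test_that("noiseless line and arc embeddings are recovered with perfect rank order", {
  panel <- list(stripe_spec("a1", "terminal_anchor_A", peak_width = 0.05, amplitude = 10),
                stripe_spec("p1", "terminal_anchor_P", peak_width = 0.05, amplitude = 10),
                stripe_spec("hk", "uniform", baseline = 5))
  sim <- simulate_embryo(200, 0, panel, seed = 2)
  nm <- log_normalize(sim$counts)
  u <- stats::setNames(sim$truth$nuclei$u, sim$truth$nuclei$nucleus_id)
  for (shape in c("line", "arc")) {
    emb <- embed_ground_truth(sim$truth, shape, noise_sd = 0, seed = 1)
    rcp <- extract_ridge_control_points(
      emb, unique(emb$cluster),
      anchor_genes = list(anterior = "a1", posterior = "p1"), nm = nm)
    curve <- fit_axis_curve(rcp$control_points, anchors = rcp)
    pos <- assign_positions(emb, curve, unique(emb$cluster))
    expect_gt(nrow(pos), 150)
    expect_rho(pos, u, 0.9999)
  }
})

test_that("automatic control points track the generating arc and anchors reject thin data", {
  f <- axis_fixture(7)
  R <- attr(f$emb, "arc_radius")
  cp <- f$curve$control_points
  dev <- abs(sqrt(cp[, 1]^2 + cp[, 2]^2) - R)
  expect_lt(max(dev), 2 * 0.5)  # within 2x the embedding noise scale
  expect_error(
    extract_ridge_control_points(f$emb, paste0("ecto_", 1:10),
      anchor_genes = list(anterior = "no_such_gene", posterior = "bi_a_1"),
      nm = f$nm),
    "anchor")
  ## blob without an elongated component is rejected
  set.seed(1)
  blob <- data.frame(nucleus_id = paste0("b", 1:300), x = rnorm(300),
                     y = rnorm(300), cluster = "k", stringsAsFactors = FALSE)
  expect_error(extract_ridge_control_points(blob, "k"), "elongated")
})
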