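## Shared fixtures, computed lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

## default-panel simulation embedded on a noisy arc (the study conditions:
## 3000 ectoderm nuclei, noise 5% of the curve length), with the axis
## reconstructed automatically and profiles built at the synthetic-scale
## near-axis threshold (3 x noise sd)
axis_fixture <- function(seed) {
  fx(paste0("axis_", seed), {
    panel <- default_gene_panel()
    gs <- panel_gene_sets(panel)
    sim <- simulate_embryo(3000, 400, panel, seed = seed)
    emb <- embed_ground_truth(sim$truth, "arc", noise_sd = 0.5, seed = seed)
    nm <- log_normalize(sim$counts)
    rcp <- extract_ridge_control_points(
      emb, paste0("ecto_", 1:10),
      anchor_genes = list(anterior = gs$anchors_anterior,
                          posterior = gs$anchors_posterior), nm = nm)
    curve <- fit_axis_curve(rcp$control_points, anchors = rcp,
                            n_polyline = 10000)
    pos <- assign_positions(emb, curve, paste0("ecto_", 1:10))
    u <- stats::setNames(sim$truth$nuclei$u, sim$truth$nuclei$nucleus_id)
    list(panel = panel, gs = gs, sim = sim, emb = emb, nm = nm,
         curve = curve, pos = pos, u = u)
  })
}

profile_fixture <- function(seed) {
  fx(paste0("prof_", seed), {
    f <- axis_fixture(seed)
    prof <- build_profile_matrix(f$nm, f$pos,
                                 smoothing_params(near_axis_threshold = 1.5))
    c(f, list(profiles = prof, derivs = first_derivative(prof)))
  })
}

## a tiny hand-built normalized matrix with two clusters and known markers
marker_fixture <- function() {
  fx("marker", {
    set.seed(42)
    n1 <- 40; n2 <- 40
    genes <- paste0("g", 1:30)
    X <- matrix(rpois(30 * (n1 + n2), 1), nrow = 30,
                dimnames = list(genes, paste0("c", 1:(n1 + n2))))
    X["g1", 1:n1] <- 5 + rpois(n1, 2)      # pan-cluster-1 marker
    X["g1", (n1 + 1):(n1 + n2)] <- 0
    X["g2", ] <- 0
    X["g2", 1:10] <- 6                      # exactly 25% of cluster 1
    nm <- log_normalize(Matrix::Matrix(X, sparse = TRUE))
    emb <- data.frame(nucleus_id = colnames(X),
                      x = rnorm(n1 + n2), y = rnorm(n1 + n2),
                      cluster = factor(rep(c("A", "B"), c(n1, n2))),
                      stringsAsFactors = FALSE)
    list(nm = nm, emb = emb, n1 = n1, n2 = n2)
  })
}

expect_rho <- function(pos, u, min) {
  rho <- abs(stats::cor(pos$position, u[pos$nucleus_id], method = "spearman"))
  expect_gte(rho, min)
  invisible(rho)
}
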