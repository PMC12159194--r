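#' Variable features, PCA, graph clustering and 2-D embedding
#'
#' The standard single-cell reduction stage, parameterized the way segmentation
#' analyses of germ-band nuclei run it: dispersion-ranked variable features,
#' per-gene scaling (clipped at |z| = 10), truncated PCA, shared-nearest-
#' neighbor graph, modularity clustering (Leiden by default, Louvain
#' selectable) at a given resolution, and a UMAP 2-D embedding. Fully seeded.
#'
#' @param nm log-normalized gene x nucleus matrix.
#' @param n_variable number of dispersion-ranked variable genes.
#' @param n_dims number of principal components (< min(genes, nuclei)).
#' @param resolution modularity resolution parameter.
#' @param seed integer seed for PCA initialization, clustering and UMAP.
#' @param k_nn neighbors for the SNN graph.
#' @param n_neighbors UMAP neighborhood size; larger values weight global over
#'   local structure (useful for small gene panels with periodic expression,
#'   where small neighborhoods fold the axis at the oscillation period).
#' @param algorithm "leiden" or "louvain".
#' @param umap compute UMAP coordinates (skipping it leaves x/y as the first
#'   two PCs).
#' @param umap_init UMAP initialization; "pca" (default) anchors the layout to
#'   the global PCA geometry, which keeps elongated manifolds from folding.
#' @param min_dist UMAP minimum embedding distance.
#' @return embedding table: data frame (nucleus_id, x, y, cluster) with
#'   attributes \code{resolution}, \code{dims}, \code{pca} (nucleus x n_dims
#'   scores) and \code{snn} (sparse SNN graph).
#' @export
reduce_and_cluster <- function(nm, n_variable = 2000, n_dims = 50,
                               resolution = 0.5, seed = 1L, k_nn = 20,
                               algorithm = c("leiden", "louvain"),
                               umap = TRUE, n_neighbors = 30,
                               umap_init = "pca", min_dist = 0.3) {
  algorithm <- match.arg(algorithm)
  if (n_dims >= min(dim(nm)))
    stop("n_dims must be < min(genes, nuclei)")
  set.seed(seed)

  ## dispersion-ranked variable features
  n <- ncol(nm)
  mu <- Matrix::rowMeans(nm)
  ex2 <- Matrix::rowSums(nm^2) / n
  v <- pmax(ex2 - mu^2, 0) * n / max(n - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  nv <- min(n_variable, sum(disp > 0))
  var_genes <- rownames(nm)[order(disp, decreasing = TRUE)][seq_len(nv)]

  X <- t(as.matrix(nm[var_genes, , drop = FALSE]))  # nuclei x genes
  X <- scale(X)
  X[is.na(X)] <- 0
  X[X > 10] <- 10; X[X < -10] <- -10

  if (n_dims < 0.5 * min(dim(X))) {
    pr <- irlba::prcomp_irlba(X, n = n_dims, center = FALSE, scale. = FALSE)
    pcs <- pr$x
  } else {
    pcs <- stats::prcomp(X, center = FALSE)$x[, seq_len(n_dims), drop = FALSE]
  }
  rownames(pcs) <- colnames(nm)

  g <- snn_graph(pcs, k = k_nn)
  set.seed(seed)
  comm <- if (algorithm == "leiden") {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10)
  } else {
    igraph::cluster_louvain(g, resolution = resolution)
  }
  cl <- factor(igraph::membership(comm))

  if (umap) {
    set.seed(seed)
    emb <- uwot::umap(pcs, n_neighbors = min(n_neighbors, nrow(pcs) - 1),
                      min_dist = min_dist, init = umap_init, n_threads = 1,
                      n_sgd_threads = 0)
  } else {
    emb <- pcs[, 1:2]
  }
  out <- data.frame(nucleus_id = colnames(nm), x = emb[, 1], y = emb[, 2],
                    cluster = cl, stringsAsFactors = FALSE)
  attr(out, "resolution") <- resolution
  attr(out, "dims") <- n_dims
  attr(out, "pca") <- pcs
  attr(out, "snn") <- g
  out
}

## shared-nearest-neighbor graph: Jaccard weights over k-NN sets, pruned at 1/15
snn_graph <- function(pcs, k = 20, prune = 1 / 15) {
  n <- nrow(pcs)
  k <- min(k, n - 1)
  nn <- RANN::nn2(pcs, k = k + 1)$nn.idx  # includes self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  shared <- methods::as(shared, "CsparseMatrix")
  jac <- shared
  jac@x <- shared@x / (2 * (k + 1) - shared@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Identify cluster marker genes by rank-sum test
#'
#' Per cluster, each gene is tested in-cluster vs all other nuclei with a
#' Wilcoxon rank-sum test (normal approximation with tie correction). Markers
#' are genes detected in strictly more than \code{min_pct_in} of the cluster's
#' nuclei, strictly less than \code{max_pct_out} of the remaining nuclei, and
#' with adjusted p-value strictly below \code{alpha} (Bonferroni over the
#' tested genes by default).
#'
#' @param nm log-normalized matrix.
#' @param emb embedding table with cluster labels.
#' @param min_pct_in,max_pct_out detection-fraction thresholds (strict).
#' @param alpha adjusted p-value threshold (strict).
#' @param adjust "bonferroni" or "BH".
#' @return data frame (gene_id, cluster, pct_in, pct_out, adjusted_p, effect),
#'   effect = difference of in/out means of log-normalized expression.
#' @export
find_cluster_markers <- function(nm, emb, min_pct_in = 0.25,
                                 max_pct_out = 0.90, alpha = 0.001,
                                 adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  cl <- emb$cluster
  if (length(unique(cl)) < 2) stop("need >= 2 clusters")
  nm <- nm[, emb$nucleus_id, drop = FALSE]
  X <- as.matrix(nm)
  res <- list()
  for (cc in levels(factor(cl))) {
    inc <- cl == cc
    n1 <- sum(inc)
    if (n1 < 3) {
      warning("cluster ", cc, " has < 3 nuclei; skipped")
      next
    }
    p <- rank_sum_pvals(X, inc)
    pct_in <- rowMeans(X[, inc, drop = FALSE] > 0)
    pct_out <- rowMeans(X[, !inc, drop = FALSE] > 0)
    adj <- stats::p.adjust(p, method = ifelse(adjust == "BH", "BH",
                                              "bonferroni"))
    eff <- rowMeans(X[, inc, drop = FALSE]) - rowMeans(X[, !inc, drop = FALSE])
    keep <- pct_in > min_pct_in & pct_out < max_pct_out & adj < alpha
    if (any(keep))
      res[[cc]] <- data.frame(gene_id = rownames(X)[keep], cluster = cc,
                              pct_in = pct_in[keep], pct_out = pct_out[keep],
                              adjusted_p = adj[keep], effect = eff[keep],
                              stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(), cluster = character(),
               pct_in = numeric(), pct_out = numeric(),
               adjusted_p = numeric(), effect = numeric())
  rownames(out) <- NULL
  out
}

## vectorized two-sided Wilcoxon rank-sum normal approximation per gene row
rank_sum_pvals <- function(X, inc) {
  n <- ncol(X); n1 <- sum(inc); n2 <- n - n1
  R <- t(apply(X, 1, rank))
  W <- rowSums(R[, inc, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ## tie correction
  tie_term <- apply(X, 1, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
  z[sig2 == 0] <- 0
  2 * stats::pnorm(-abs(z))
}

#' Flag clusters driven by low gene/molecule counts
#'
#' Flags clusters whose median detected-gene count and median molecule count
#' both fall below \code{fraction} of the global medians — the signature of a
#' pseudocluster (a cluster reflecting data quality, not a cell state). Flags
#' are advisory; exclusion is the caller's choice.
#'
#' @param m count matrix.
#' @param emb embedding table with cluster labels.
#' @param fraction threshold fraction of the global medians (default 0.7).
#' @return data frame (cluster, median_genes, median_molecules, flagged).
#' @export
diagnose_low_quality_clusters <- function(m, emb, fraction = 0.7) {
  m <- Matrix::drop0(m[, emb$nucleus_id, drop = FALSE])
  n_genes <- diff(m@p)
  n_mol <- Matrix::colSums(m)
  g_med <- stats::median(n_genes); m_med <- stats::median(n_mol)
  cl <- as.character(emb$cluster)
  med_g <- tapply(n_genes, cl, stats::median)
  med_m <- tapply(n_mol, cl, stats::median)
  data.frame(cluster = names(med_g),
             median_genes = as.numeric(med_g),
             median_molecules = as.numeric(med_m[names(med_g)]),
             flagged = as.numeric(med_g) < fraction * g_med &
                       as.numeric(med_m[names(med_g)]) < fraction * m_med,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Randomly subsample nuclei
#'
#' Draws \code{trials} independent uniform without-replacement samples of
#' \code{n} nuclei (columns). Per-trial seeds are derived deterministically
#' from the master seed, so the full set of subsets is reproducible.
#'
#' @param m count matrix.
#' @param n nuclei per subsample (<= ncol(m)).
#' @param trials number of subsamples.
#' @param seed master seed.
#' @return list of \code{trials} column-subset matrices.
#' @export
subsample_nuclei <- function(m, n, trials = 10, seed = 1L) {
  if (n > ncol(m)) stop("n exceeds available nuclei (", ncol(m), ")")
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, trials)
  lapply(seq_len(trials), function(t) {
    set.seed(trial_seeds[t])
    m[, sort(sample.int(ncol(m), n)), drop = FALSE]
  })
}
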