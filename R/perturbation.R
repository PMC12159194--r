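#' Randomize gene expression within a cluster
#'
#' For each gene independently, applies a uniform random permutation to its
#' expression values across the target cluster's nuclei (or across an
#' independently sampled fraction of them), leaving all other values untouched.
#' Per-gene value multisets within the cluster are conserved exactly.
#'
#' @param nm normalized matrix.
#' @param emb embedding table with cluster labels.
#' @param cluster target cluster label.
#' @param genes genes to randomize.
#' @param fraction fraction of cluster nuclei permuted per gene (in (0, 1]);
#'   the subset is drawn independently for each gene.
#' @param seed integer seed.
#' @return the perturbed matrix (same shape and dimnames).
#' @export
randomize_cluster_expression <- function(nm, emb, cluster, genes,
                                         fraction = 1, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  cols <- emb$nucleus_id[emb$cluster == cluster]
  if (length(cols) < 2) stop("cluster '", cluster, "' has < 2 nuclei")
  genes <- intersect(genes, rownames(nm))
  if (!length(genes)) stop("no target genes present in the matrix")
  set.seed(seed)
  ci <- match(cols, colnames(nm))
  sub <- as.matrix(nm[genes, ci, drop = FALSE])
  nc <- length(ci)
  for (g in seq_len(nrow(sub))) {
    tgt <- if (fraction < 1) sample.int(nc, max(2, round(fraction * nc)))
           else seq_len(nc)
    sub[g, tgt] <- sub[g, tgt[sample.int(length(tgt))]]
  }
  nm[genes, ci] <- sub
  nm
}

#' Score recovery of the axis ordering
#'
#' \code{global_rho} is the absolute Spearman correlation between recovered and
#' reference positions (absolute, because a fresh embedding gives the axis no
#' intrinsic orientation). \code{per_cluster_continuity} is, per cluster, the
#' mean over nuclei of the fraction of each nucleus' k nearest neighbors in
#' the recovered space that are also reference-position neighbors, i.e. among
#' its k_ref nearest nuclei along the reference axis — a quantitative stand-in
#' for judging an embedding "continuous" along the axis by eye. k_ref is wider
#' than k because a 2-D neighborhood of size k spans a longer stretch of the
#' 1-D axis than the k axis-nearest nuclei; with k_ref = k the score floors
#' near zero even for a perfect embedding.
#'
#' @param recovered either a position table (nucleus_id, position) or an
#'   embedding table (nucleus_id, x, y).
#' @param reference named numeric vector of reference positions (ground-truth
#'   latent positions or pre-perturbation positions), names = nucleus ids.
#' @param k neighborhood size (default 15).
#' @param k_ref reference-axis neighborhood size (default 10 * k).
#' @param clusters optional named cluster labels (names = nucleus ids) for the
#'   continuity breakdown; a single "all" group otherwise.
#' @return list(global_rho, per_cluster_continuity, k, n).
#' @export
axis_recovery_score <- function(recovered, reference, k = 15, clusters = NULL,
                                k_ref = 10 * k) {
  reference <- reference[is.finite(reference)]
  ids <- intersect(recovered$nucleus_id, names(reference))
  if (length(ids) < 10) stop("fewer than 10 shared nuclei")
  rec <- recovered[match(ids, recovered$nucleus_id), , drop = FALSE]
  ref <- reference[ids]

  if (!is.null(rec$position)) {
    rec_space <- matrix(rec$position, ncol = 1)
    rho <- abs(stats::cor(rec$position, ref, method = "spearman"))
  } else {
    rec_space <- cbind(rec$x, rec$y)
    ## orientation-free 1-D summary: first principal axis of the embedding
    pc1 <- stats::prcomp(rec_space)$x[, 1]
    rho <- abs(stats::cor(pc1, ref, method = "spearman"))
  }
  k <- min(k, length(ids) - 1)
  k_ref <- min(k_ref, length(ids) - 1)
  nn_rec <- RANN::nn2(rec_space, k = k + 1)$nn.idx[, -1, drop = FALSE]
  nn_ref <- RANN::nn2(matrix(ref, ncol = 1),
                      k = k_ref + 1)$nn.idx[, -1, drop = FALSE]
  overlap <- vapply(seq_along(ids), function(i)
    length(intersect(nn_rec[i, ], nn_ref[i, ])) / k, 0)
  cl <- if (is.null(clusters)) rep("all", length(ids))
        else as.character(clusters[ids])
  cont <- tapply(overlap, cl, mean)
  list(global_rho = as.numeric(rho),
       per_cluster_continuity = cont, k = k, n = length(ids))
}

## shared re-analysis path: reduce/cluster/embed a matrix, reconstruct the
## axis, and return recovered positions (falling back to the first principal
## axis of the 2-D embedding when ridge tracing rejects the point cloud).
recover_positions <- function(nm, seed, resolution = 0.5, n_dims = NULL,
                              anchor_genes = NULL, n_neighbors = 200,
                              min_dist = 0.1) {
  n_dims <- if (is.null(n_dims)) min(50, min(dim(nm)) - 1) else n_dims
  emb <- reduce_and_cluster(nm, n_variable = min(2000, nrow(nm)),
                            n_dims = n_dims, resolution = resolution,
                            seed = seed, n_neighbors = n_neighbors,
                            min_dist = min_dist)
  axis_cl <- levels(factor(emb$cluster))
  pos <- tryCatch({
    if (!is.null(anchor_genes) &&
        !all(unlist(anchor_genes) %in% rownames(nm))) anchor_genes <- NULL
    rcp <- extract_ridge_control_points(emb, axis_cl,
                                        anchor_genes = anchor_genes, nm = nm)
    curve <- fit_axis_curve(rcp$control_points, anchors = rcp,
                            n_polyline = 10000)
    assign_positions(emb, curve, axis_cl)
  }, error = function(e) {
    pc1 <- stats::prcomp(cbind(emb$x, emb$y))$x[, 1]
    data.frame(nucleus_id = emb$nucleus_id, position = pc1,
               distance = 0, stringsAsFactors = FALSE)
  })
  list(positions = pos, embedding = emb)
}

#' Submatrix A/B axis-reconstruction contrast
#'
#' Re-runs the clustering + axis reconstruction + position assignment pipeline
#' on submatrix A (selected genes) and submatrix B (all other genes, same
#' nuclei) and scores each against reference positions — the test of whether
#' the selected genes carry the axial information.
#'
#' @param nm normalized matrix.
#' @param selected_genes gene ids defining submatrix A.
#' @param axis_nuclei nucleus ids used for both submatrices.
#' @param reference named reference positions.
#' @param seed seed shared by both re-analyses.
#' @param resolution clustering resolution.
#' @param anchor_genes optional anchors for axis orientation (used only where
#'   present in a submatrix).
#' @param n_neighbors UMAP neighborhood used for both re-analyses (large, so
#'   the re-embedding preserves global axis topology for small gene panels).
#' @return list(score_A, score_B) of \code{axis_recovery_score} results.
#' @export
run_submatrix_experiment <- function(nm, selected_genes, axis_nuclei,
                                     reference, seed = 1L, resolution = 0.5,
                                     anchor_genes = NULL, n_neighbors = 200) {
  sm <- build_submatrices(nm, axis_nuclei, selected_genes)
  recA <- recover_positions(sm$A, seed = seed, resolution = resolution,
                            anchor_genes = anchor_genes,
                            n_neighbors = n_neighbors)
  recB <- recover_positions(sm$B, seed = seed, resolution = resolution,
                            anchor_genes = anchor_genes,
                            n_neighbors = n_neighbors)
  list(score_A = axis_recovery_score(recA$positions, reference),
       score_B = axis_recovery_score(recB$positions, reference))
}

#' Graded in-cluster randomization sweep
#'
#' For each (fraction, seed) pair, randomizes the target genes within the
#' target cluster at that fraction, re-embeds the matrix with the seed shared
#' with the unperturbed run, and scores continuity against the reference.
#' Rows with fraction 0 are the unperturbed baseline for each seed.
#'
#' @param nm normalized matrix.
#' @param emb embedding table (cluster labels define the target and the
#'   continuity breakdown).
#' @param cluster target cluster.
#' @param genes genes to randomize.
#' @param fractions numeric fractions in (0, 1]; empty gives an empty table.
#' @param seeds integer replicate seeds.
#' @param reference named reference positions.
#' @param k continuity neighborhood size.
#' @param k_ref reference-axis neighborhood size.
#' @param include_baseline add fraction-0 unperturbed rows.
#' @param n_neighbors,min_dist re-embedding UMAP parameters; the sweep uses a
#'   standard local neighborhood (unlike the global settings of the submatrix
#'   harness) because within-cluster discontinuity is a local feature that a
#'   very large neighborhood smooths away.
#' @return data frame (fraction, seed, global_rho, target_continuity,
#'   other_continuity).
#' @export
run_randomization_sweep <- function(nm, emb, cluster, genes, fractions,
                                    seeds = 1L, reference, k = 15,
                                    k_ref = 10 * k, include_baseline = TRUE,
                                    n_neighbors = 30, min_dist = 0.3) {
  clusters <- stats::setNames(as.character(emb$cluster), emb$nucleus_id)
  score_one <- function(mat, seed) {
    rec <- recover_positions(mat, seed = seed, n_neighbors = n_neighbors,
                             min_dist = min_dist)
    sc <- axis_recovery_score(rec$embedding, reference, k = k, k_ref = k_ref,
                              clusters = clusters)
    cont <- sc$per_cluster_continuity
    tgt <- cont[[as.character(cluster)]]
    oth <- mean(cont[setdiff(names(cont), as.character(cluster))])
    c(global_rho = sc$global_rho, target_continuity = tgt,
      other_continuity = oth)
  }
  if (!length(fractions))
    return(data.frame(fraction = numeric(), seed = integer(),
                      global_rho = numeric(), target_continuity = numeric(),
                      other_continuity = numeric()))
  rows <- list()
  for (seed in seeds) {
    if (include_baseline)
      rows[[length(rows) + 1L]] <-
        c(fraction = 0, seed = seed, score_one(nm, seed))
    for (f in fractions) {
      pert <- randomize_cluster_expression(nm, emb, cluster, genes,
                                           fraction = f, seed = seed)
      rows[[length(rows) + 1L]] <-
        c(fraction = f, seed = seed, score_one(pert, seed))
    }
  }
  if (!length(rows))
    return(data.frame(fraction = numeric(), seed = integer(),
                      global_rho = numeric(), target_continuity = numeric(),
                      other_continuity = numeric()))
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
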