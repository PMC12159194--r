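#' Exclude sparsely expressed genes by minimum expression gap
#'
#' For each gene, computes the minimum pairwise distance along the
#' reconstructed axis between nuclei expressing it (nonzero); genes with fewer
#' than two expressing nuclei get the full axis length as a sentinel. Ward
#' (ward.D2) hierarchical clustering of this scalar splits the genes into two
#' groups and the group with the larger mean gap — genes expressed in a few
#' scattered nuclei, indistinguishable from region-specific expression by
#' profile shape alone — is excluded.
#'
#' @param nm normalized matrix.
#' @param pos nucleus position table (terminus attribute used for the axis
#'   length sentinel).
#' @return list(retained, excluded, min_expr_gap) of gene id vectors and the
#'   named gap vector.
#' @export
sparse_gene_filter <- function(nm, pos) {
  ids <- intersect(pos$nucleus_id, colnames(nm))
  if (!length(ids)) stop("no shared nucleus IDs")
  term <- attr(pos, "terminus")
  axis_len <- if (!is.null(term)) diff(term) else diff(range(pos$position))
  X <- nm[, pos$nucleus_id, drop = FALSE]
  p <- pos$position
  gap <- apply(X, 1, function(x) {
    pe <- sort(p[x != 0])
    if (length(pe) < 2) axis_len else min(diff(pe))
  })
  hc <- stats::hclust(stats::dist(gap), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  mg <- tapply(gap, grp, mean)
  sparse_grp <- as.integer(names(mg)[which.max(mg)])
  excluded <- rownames(nm)[grp == sparse_grp]
  if (length(excluded) == nrow(nm)) stop("all genes classified sparse")
  list(retained = setdiff(rownames(nm), excluded), excluded = excluded,
       min_expr_gap = gap)
}

#' Profile summary features for pattern-gene selection
#'
#' @param profiles gene x subdivision profile matrix.
#' @return data frame (gene_id, mean, diff) where diff = max - min of the
#'   profile values.
#' @export
compute_pattern_features <- function(profiles) {
  data.frame(gene_id = rownames(profiles),
             mean = rowMeans(profiles),
             diff = apply(profiles, 1, max) - apply(profiles, 1, min),
             stringsAsFactors = FALSE)
}

#' Two-round hierarchical-clustering selection of pattern genes
#'
#' Round 1: Ward (ward.D2) clustering of the genes on (mean, diff) profile
#' features (z-scored by default), cut into \code{k1} groups. Groups whose
#' centroid has a clearly large diff AND mean below the grand median of means
#' — relatively low expression with a large dynamic range, the signature of
#' spatially restricted genes — are kept (or an explicit group-id
#' \code{whitelist} overrides the rule). "Clearly large" means above the grand
#' median of diffs plus \code{mad_factor} median absolute deviations
#' (\code{rule = "median_mad"}, the default): because max - min is
#' right-skewed, the centroid (a mean) of a typical unpatterned group sits
#' slightly above the grand median, so a bare median cut
#' (\code{rule = "median"}, also available) admits much of the flat bulk.
#' Round 2: each kept group is
#' re-clustered into k subgroups (k chosen by maximum average silhouette over
#' \code{k2_range}, ties to the smaller k) and subgroups are kept by the same
#' centroid rule. Selected genes are the union of kept subgroups.
#'
#' @param features data frame from \code{compute_pattern_features}.
#' @param k1 round-1 group count (default 12).
#' @param k2_range candidate subgroup counts (default 2:5).
#' @param rule "median_mad" (default), "median" or "whitelist".
#' @param whitelist round-1 group ids kept in whitelist mode (all their genes
#'   are selected).
#' @param standardize z-score features before clustering.
#' @param mad_factor MADs above the grand median a centroid diff must clear
#'   under the default rule.
#' @return data frame (gene_id, round1_group, round2_group, selected).
#' @export
two_round_select <- function(features, k1 = 12, k2_range = 2:5,
                             rule = c("median_mad", "median", "whitelist"),
                             whitelist = NULL, standardize = TRUE,
                             mad_factor = 2) {
  rule <- match.arg(rule)
  if (k1 < 2) stop("k1 must be >= 2")
  if (k1 > nrow(features)) stop("k1 exceeds the number of genes")
  F <- cbind(features$mean, features$diff)
  Fc <- if (standardize) scale(F) else F
  Fc[is.na(Fc)] <- 0
  hc <- stats::hclust(stats::dist(Fc), method = "ward.D2")
  g1 <- stats::cutree(hc, k = k1)

  med_mean <- stats::median(features$mean)
  med_diff <- stats::median(features$diff)
  diff_cut <- if (rule == "median_mad")
    med_diff + mad_factor * stats::mad(features$diff) else med_diff
  passes <- function(idx) {
    mean(features$diff[idx]) > diff_cut && mean(features$mean[idx]) < med_mean
  }
  kept1 <- if (rule == "whitelist") {
    intersect(unique(g1), as.integer(whitelist))
  } else {
    Filter(function(g) passes(which(g1 == g)), unique(g1))
  }

  g2 <- rep(NA_integer_, nrow(features))
  selected <- rep(FALSE, nrow(features))
  for (g in kept1) {
    idx <- which(g1 == g)
    if (rule == "whitelist") { selected[idx] <- TRUE; next }
    if (length(idx) < 3) { selected[idx] <- TRUE; g2[idx] <- 1L; next }
    hc2 <- stats::hclust(stats::dist(Fc[idx, , drop = FALSE]),
                         method = "ward.D2")
    ks <- k2_range[k2_range >= 2 & k2_range <= length(idx) - 1]
    if (!length(ks)) { selected[idx] <- TRUE; g2[idx] <- 1L; next }
    sil <- vapply(ks, function(k) {
      ct <- stats::cutree(hc2, k = k)
      mean(cluster::silhouette(ct, stats::dist(Fc[idx, , drop = FALSE]))[, 3])
    }, 0)
    k_best <- ks[which.max(sil)]  # which.max takes the first: ties -> smaller k
    sub <- stats::cutree(hc2, k = k_best)
    g2[idx] <- sub
    for (s in unique(sub)) {
      sidx <- idx[sub == s]
      if (passes(sidx)) selected[sidx] <- TRUE
    }
  }
  data.frame(gene_id = features$gene_id, round1_group = g1, round2_group = g2,
             selected = selected, stringsAsFactors = FALSE)
}

#' Split the matrix into selected / complement gene submatrices
#'
#' Submatrix A holds the selected genes over the axis nuclei; submatrix B
#' holds every other gene over the same nuclei in the same order. A and B
#' partition the gene universe.
#'
#' @param nm normalized matrix.
#' @param axis_nuclei nucleus ids (columns of both submatrices).
#' @param selected_genes gene ids for submatrix A (proper non-empty subset).
#' @return list(A, B).
#' @export
build_submatrices <- function(nm, axis_nuclei, selected_genes) {
  if (!length(selected_genes)) stop("empty selected gene set")
  if (!all(selected_genes %in% rownames(nm)))
    stop("selected genes absent from the matrix")
  comp <- setdiff(rownames(nm), selected_genes)
  if (!length(comp)) stop("complement gene set is empty")
  if (!all(axis_nuclei %in% colnames(nm)))
    stop("axis nuclei absent from the matrix")
  list(A = nm[selected_genes, axis_nuclei, drop = FALSE],
       B = nm[comp, axis_nuclei, drop = FALSE])
}
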