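#' First derivative of an expression profile
#'
#' Central differences at interior positions, d[i] = (x[i+1] - x[i-1]) / 2, and
#' single-sided differences at the termini (d[1] = x[2] - x[1],
#' d[n] = x[n] - x[n-1]); positive values mean expression increasing toward the
#' posterior. Derivative extremes mark expression-domain boundaries; zeros mark
#' peaks.
#'
#' @param x numeric profile vector (or a gene x position matrix, handled
#'   row-wise).
#' @return derivative vector (or matrix) of the same shape.
#' @export
first_derivative <- function(x) {
  if (is.matrix(x)) {
    d <- t(apply(x, 1, first_derivative))
    dimnames(d) <- dimnames(x)
    return(d)
  }
  if (any(!is.finite(x))) stop("non-finite profile values")
  n <- length(x)
  if (n < 2) stop("profile too short")
  c(x[2] - x[1],
    if (n > 2) (x[3:n] - x[1:(n - 2)]) / 2,
    x[n] - x[n - 1])
}

#' Per-position table of extreme derivative values
#'
#' At each axis position the derivative values are sorted and the k highest
#' and k lowest are returned with their genes (ties broken by gene id, so the
#' table is deterministic).
#'
#' @param derivs gene x position derivative matrix.
#' @param k extremes per side (<= gene count).
#' @return data frame (position, side, rank, gene_id, value).
#' @export
top_extremes_table <- function(derivs, k = 50) {
  if (k > nrow(derivs)) stop("k exceeds the gene count")
  out <- lapply(seq_len(ncol(derivs)), function(j) {
    v <- derivs[, j]
    o_hi <- order(-v, rownames(derivs))[seq_len(k)]
    o_lo <- order(v, rownames(derivs))[seq_len(k)]
    rbind(data.frame(position = j, side = "high", rank = seq_len(k),
                     gene_id = rownames(derivs)[o_hi], value = v[o_hi],
                     stringsAsFactors = FALSE),
          data.frame(position = j, side = "low", rank = seq_len(k),
                     gene_id = rownames(derivs)[o_lo], value = v[o_lo],
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Position-position Pearson correlation of derivative profiles
#'
#' Correlates the axis positions across a gene subset: column j of the map is
#' position j's derivative values over the genes. Repetitive (segmental)
#' pattern shows up as periodic positive/negative off-diagonal bands.
#'
#' @param derivs gene x position derivative matrix.
#' @param genes optional gene subset (>= 3 genes).
#' @return symmetric position x position correlation matrix; zero-variance
#'   positions give NA rows/columns.
#' @export
position_correlation <- function(derivs, genes = NULL) {
  if (!is.null(genes)) derivs <- derivs[genes, , drop = FALSE]
  if (nrow(derivs) < 3) stop("need >= 3 genes")
  suppressWarnings(stats::cor(derivs))
}

#' Group genes by local derivative correlation within a region
#'
#' Within a closed position interval, genes whose profile maximum inside the
#' region is below \code{max_threshold} are excluded (strictly less than);
#' the remaining genes are represented by their rows of the gene x gene
#' Pearson correlation matrix of region-restricted derivative values, and Ward
#' (ward.D2) clustering of the Euclidean distances between those rows is cut
#' into \code{n_groups}.
#'
#' @param profiles gene x position profile matrix.
#' @param derivs matching derivative matrix.
#' @param region c(start, end) subdivision indices (1-based, closed).
#' @param max_threshold minimum in-region profile maximum (default 0.2).
#' @param n_groups number of groups to cut.
#' @param cor_transform "rows" (Euclidean distance between correlation-matrix
#'   rows, the default) or "one_minus_r" (sqrt(2 * (1 - r))).
#' @return named integer vector of group labels for the retained genes.
#' @export
region_gene_groups <- function(profiles, derivs, region, max_threshold = 0.2,
                               n_groups, cor_transform = c("rows", "one_minus_r")) {
  cor_transform <- match.arg(cor_transform)
  if (region[1] < 1 || region[2] > ncol(profiles) || region[1] >= region[2])
    stop("invalid region")
  idx <- region[1]:region[2]
  keep <- apply(profiles[, idx, drop = FALSE], 1, max) >= max_threshold
  D <- derivs[keep, idx, drop = FALSE]
  ## zero-variance genes have no correlation signature in the region
  vr <- apply(D, 1, stats::var)
  if (any(vr == 0)) {
    warning(sum(vr == 0), " gene(s) with zero derivative variance in region dropped")
    D <- D[vr > 0, , drop = FALSE]
  }
  if (nrow(D) < 2) stop("fewer than 2 genes survive the region filter")
  R <- stats::cor(t(D))
  dd <- if (cor_transform == "rows") stats::dist(R)
        else stats::as.dist(sqrt(2 * (1 - R)))
  hc <- stats::hclust(dd, method = "ward.D2")
  stats::cutree(hc, k = min(n_groups, nrow(D)))
}

#' Single-nucleus gene-gene correlation network within a position window
#'
#' Restricts to nuclei whose axis subdivision falls in the window (closed),
#' drops genes expressed in at most \code{min_expr_frac} of those nuclei
#' (strictly more required), correlates gene pairs over single-nucleus
#' expression and returns edges with |r| strictly above the threshold.
#'
#' @param nm normalized matrix.
#' @param pos nucleus position table (terminus attribute required to map arc
#'   positions to subdivisions 1..80).
#' @param window c(lo, hi) subdivision interval.
#' @param genes gene subset to consider.
#' @param min_expr_frac detection-fraction filter (strict, default 0.10).
#' @param r_threshold absolute correlation threshold (strict, default 0.5).
#' @param n_subdivisions subdivision count of the axis (default 80).
#' @return data frame (gene_a, gene_b, r, sign, window).
#' @export
gene_pair_network <- function(nm, pos, window, genes,
                              min_expr_frac = 0.10, r_threshold = 0.5,
                              n_subdivisions = 80) {
  term <- attr(pos, "terminus")
  if (is.null(term)) stop("position table lacks terminus attribute")
  sub <- 1 + (n_subdivisions - 1) * (pos$position - term[1]) / diff(term)
  inw <- sub >= window[1] & sub <= window[2]
  if (sum(inw) < 10) stop("fewer than 10 nuclei in window")
  ids <- pos$nucleus_id[inw]
  genes <- intersect(genes, rownames(nm))
  X <- as.matrix(nm[genes, ids, drop = FALSE])
  frac <- rowMeans(X > 0)
  X <- X[frac > min_expr_frac, , drop = FALSE]
  if (nrow(X) < 2)
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), sign = character(), window = character()))
  R <- suppressWarnings(stats::cor(t(X)))
  ut <- which(upper.tri(R) & abs(R) > r_threshold & !is.na(R), arr.ind = TRUE)
  data.frame(gene_a = rownames(X)[ut[, 1]], gene_b = rownames(X)[ut[, 2]],
             r = R[ut], sign = ifelse(R[ut] > 0, "positive", "negative"),
             window = paste(window, collapse = "-"),
             stringsAsFactors = FALSE)
}
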