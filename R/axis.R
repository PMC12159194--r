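#' Extract ordered control points along the ectoderm density ridge
#'
#' Reconstructs the backbone of the elongated ectoderm point cloud in a 2-D
#' embedding. In manual mode (\code{manual_points} supplied) the given ordered
#' points are used verbatim and its endpoints become the termini. In automatic
#' mode a principal-curve iteration (initialized from the first principal axis,
#' alternating projection and local smoothing) traces the ridge; terminal
#' anchors are located at the 2-D kernel-density peaks of nuclei expressing the
#' anterior and posterior marker gene sets, the traced curve is trimmed between
#' the anchor projections and the anchors become the terminal control points.
#'
#' @param emb embedding table (nucleus_id, x, y, cluster).
#' @param axis_clusters cluster labels forming the axis supercluster.
#' @param anchor_genes list(anterior = , posterior = ) of gene id vectors, or
#'   NULL to orient by the first principal axis (orientation then arbitrary).
#' @param nm normalized matrix (needed when anchor_genes given).
#' @param manual_points optional ordered 2-column matrix of control points
#'   (manual mode, returned verbatim).
#' @param n_control number of control points placed along the traced ridge.
#' @param min_elongation reject point clouds whose principal-axis sd ratio is
#'   below this (no elongated component to trace).
#' @return list(control_points, anterior_anchor, posterior_anchor).
#' @export
extract_ridge_control_points <- function(emb, axis_clusters,
                                         anchor_genes = NULL, nm = NULL,
                                         manual_points = NULL,
                                         n_control = 15,
                                         min_elongation = 1.5) {
  if (!is.null(manual_points)) {
    mp <- as.matrix(manual_points)
    if (ncol(mp) != 2 || nrow(mp) < 2) stop("manual_points must be n x 2")
    return(list(control_points = mp, anterior_anchor = mp[1, ],
                posterior_anchor = mp[nrow(mp), ]))
  }
  if (!length(axis_clusters)) stop("axis_clusters must be non-empty")
  sel <- emb$cluster %in% axis_clusters
  if (!any(sel)) stop("no nuclei in the given axis clusters")
  pts <- cbind(emb$x[sel], emb$y[sel])

  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[1] / max(sv[2], .Machine$double.eps) < min_elongation)
    stop("ridge tracing failed: no elongated component ",
         "(principal-axis sd ratio ", round(sv[1] / sv[2], 2), " < ",
         min_elongation, ")")

  curve <- principal_curve_trace(pts)

  anchors <- NULL
  if (!is.null(anchor_genes)) {
    if (is.null(nm)) stop("nm required to locate anchor gene density peaks")
    ids <- emb$nucleus_id[sel]
    anchors <- list(
      anterior = density_peak(pts, expressing(nm, anchor_genes$anterior, ids)),
      posterior = density_peak(pts, expressing(nm, anchor_genes$posterior, ids)))
    ## orient the traced curve anterior -> posterior
    d_head <- sum((curve$points[1, ] - anchors$anterior)^2)
    d_tail <- sum((curve$points[nrow(curve$points), ] - anchors$anterior)^2)
    if (d_head > d_tail) curve$points <- curve$points[nrow(curve$points):1, ]
  }

  ## place control points evenly in arc length along the traced ridge
  arc <- c(0, cumsum(sqrt(rowSums(diff(curve$points)^2))))
  targets <- seq(0, max(arc), length.out = n_control)
  cp <- cbind(stats::approx(arc, curve$points[, 1], xout = targets)$y,
              stats::approx(arc, curve$points[, 2], xout = targets)$y)

  if (!is.null(anchors)) {
    ## trim to between the anchors' projections and pin the termini
    pos <- polyline_positions(cp)
    pa <- pos[nearest_point_index(rbind(anchors$anterior), cp)]
    pp <- pos[nearest_point_index(rbind(anchors$posterior), cp)]
    keep <- pos > pa & pos < pp
    cp <- rbind(anchors$anterior, cp[keep, , drop = FALSE], anchors$posterior)
    a_anchor <- anchors$anterior; p_anchor <- anchors$posterior
  } else {
    a_anchor <- cp[1, ]; p_anchor <- cp[nrow(cp), ]
  }
  rownames(cp) <- NULL
  list(control_points = unname(cp), anterior_anchor = as.numeric(a_anchor),
       posterior_anchor = as.numeric(p_anchor))
}

expressing <- function(nm, genes, ids) {
  genes <- intersect(genes, rownames(nm))
  if (!length(genes)) stop("anchor genes absent from matrix")
  w <- Matrix::colSums(nm[genes, ids, drop = FALSE])
  if (sum(w > 0) < 5)
    stop("anchor ill-defined: marker expressed in ", sum(w > 0),
         " nuclei (< 5)")
  as.numeric(w)
}

## location of the expression-weighted 2-D KDE maximum. Weighting by the
## summed marker expression (rather than flagging any nonzero nucleus) keeps
## stray single-count expressers in dense embedding regions from out-peaking
## the true marker domain. Bandwidth: normal reference rule on the expressing
## points, the kde2d convention.
density_peak <- function(pts, w, grid_n = 60) {
  p <- pts[w > 0, , drop = FALSE]
  wp <- w[w > 0]
  h <- c(MASS::bandwidth.nrd(p[, 1]), MASS::bandwidth.nrd(p[, 2]))
  h[!is.finite(h) | h <= 0] <- diff(range(pts)) / 20 + 1e-9
  h <- h / 4  # kde2d divides its bandwidth by 4 internally
  gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = grid_n)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = grid_n)
  Kx <- outer(gx, p[, 1], function(a, b) stats::dnorm(a - b, sd = h[1]))
  Ky <- outer(p[, 2], gy, function(a, b) stats::dnorm(a - b, sd = h[2]))
  z <- Kx %*% (wp * Ky)
  ij <- which(z == max(z), arr.ind = TRUE)[1, ]
  c(gx[ij[1]], gy[ij[2]])
}

## Hastie-Stuetzle-style principal curve: project points onto the current
## polyline, smooth coordinates against arc-length parameter, iterate.
principal_curve_trace <- function(pts, n_iter = 6, span = 0.3, grid_n = 200) {
  ctr <- colMeans(pts)
  v1 <- svd(scale(pts, scale = FALSE))$v[, 1]
  lam <- as.numeric(scale(pts, scale = FALSE) %*% v1)
  for (it in seq_len(n_iter)) {
    o <- order(lam)
    lo_x <- stats::loess(pts[o, 1] ~ lam[o], span = span, degree = 2)
    lo_y <- stats::loess(pts[o, 2] ~ lam[o], span = span, degree = 2)
    grid <- seq(min(lam), max(lam), length.out = grid_n)
    cx <- stats::predict(lo_x, grid)
    cy <- stats::predict(lo_y, grid)
    ok <- is.finite(cx) & is.finite(cy)
    poly <- cbind(cx[ok], cy[ok])
    idx <- nearest_point_index(pts, poly)
    lam <- polyline_positions(poly)[idx]
    ## deterministic de-tie to keep loess happy
    lam <- lam + 1e-9 * seq_along(lam) / length(lam)
  }
  list(points = poly, lambda = lam)
}

polyline_positions <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Exact nearest polyline point for a set of query points
#'
#' Chunked vectorized exact search; ties broken by the lowest polyline index.
#'
#' @param pts n x 2 query points.
#' @param poly m x 2 polyline points.
#' @param chunk queries per block (memory control).
#' @return integer vector of nearest polyline indices.
#' @export
nearest_point_index <- function(pts, poly, chunk = 512L) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  q2 <- rowSums(poly^2)
  out <- integer(nrow(pts))
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    P <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), q2, "+") - 2 * P %*% t(poly)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Fit the axis spline and discretize it by arc length
#'
#' Fits an interpolating natural cubic spline through the ordered control
#' points (chord-length parametrization of x(t), y(t)), appends a linear
#' extension at each terminus along the terminal tangent, densifies the
#' extended curve and resamples it to \code{n_polyline} points evenly spaced in
#' arc length. Positions are cumulative arc length from the anterior end
#' (summed over neighboring polyline points).
#'
#' @param control_points ordered n x 2 matrix (>= 4 points).
#' @param anchors optional list(anterior_anchor, posterior_anchor) as returned
#'   by \code{extract_ridge_control_points} (recorded on the object).
#' @param n_polyline number of evenly spaced polyline points (default 10,000).
#' @param extension_frac extension length at each terminus as a fraction of
#'   the terminus-to-terminus curve length.
#' @return an \code{ap_axis} object: list(control_points, polyline, position,
#'   terminus = c(anterior, posterior), on_extension, extension_points, ...).
#' @export
fit_axis_curve <- function(control_points, anchors = NULL, n_polyline = 10000,
                           extension_frac = 0.1) {
  cp <- as.matrix(control_points)
  if (nrow(cp) < 4) stop("need >= 4 control points")
  ## drop consecutive duplicates (zero chord steps break the parametrization)
  dd <- c(TRUE, rowSums(diff(cp)^2) > 0)
  cp <- cp[dd, , drop = FALSE]
  if (nrow(cp) < 4) stop("need >= 4 distinct control points")

  tt <- polyline_positions(cp)
  fx <- stats::splinefun(tt, cp[, 1], method = "natural")
  fy <- stats::splinefun(tt, cp[, 2], method = "natural")
  dense_t <- seq(0, max(tt), length.out = max(10 * n_polyline, 2000))
  dx <- fx(dense_t); dy <- fy(dense_t)
  curve <- cbind(dx, dy)
  curve_len <- sum(sqrt(rowSums(diff(curve)^2)))

  ## linear extensions along terminal tangents
  ext_len <- extension_frac * curve_len
  tan_a <- c(fx(0, deriv = 1), fy(0, deriv = 1))
  tan_a <- tan_a / sqrt(sum(tan_a^2))
  tan_p <- c(fx(max(tt), deriv = 1), fy(max(tt), deriv = 1))
  tan_p <- tan_p / sqrt(sum(tan_p^2))
  ext_a_pt <- curve[1, ] - ext_len * tan_a
  ext_p_pt <- curve[nrow(curve), ] + ext_len * tan_p
  n_ext <- max(2, ceiling(nrow(curve) * extension_frac))
  ext_a <- cbind(seq(ext_a_pt[1], curve[1, 1], length.out = n_ext),
                 seq(ext_a_pt[2], curve[1, 2], length.out = n_ext))
  ext_p <- cbind(seq(curve[nrow(curve), 1], ext_p_pt[1], length.out = n_ext),
                 seq(curve[nrow(curve), 2], ext_p_pt[2], length.out = n_ext))
  full <- rbind(ext_a[-n_ext, , drop = FALSE], curve,
                ext_p[-1, , drop = FALSE])

  ## resample to n_polyline points even in arc length
  arc <- polyline_positions(full)
  targets <- seq(0, max(arc), length.out = n_polyline)
  keep <- !duplicated(arc)
  poly <- cbind(stats::approx(arc[keep], full[keep, 1], xout = targets)$y,
                stats::approx(arc[keep], full[keep, 2], xout = targets)$y)
  position <- polyline_positions(poly)

  ## terminus arc positions: nearest polyline point to each true terminus
  i_a <- nearest_point_index(rbind(curve[1, ]), poly)
  i_p <- nearest_point_index(rbind(curve[nrow(curve), ]), poly)
  terminus <- c(anterior = position[i_a], posterior = position[i_p])
  on_ext <- position < terminus[1] | position > terminus[2]

  ## self-intersection heuristic: resampled spacing should stay near-uniform
  sp <- sqrt(rowSums(diff(poly)^2))
  if (max(abs(sp - mean(sp))) > 0.01 * mean(sp))
    warning("polyline spacing deviates > 1% from uniform; ",
            "curve may be badly conditioned")

  structure(list(control_points = cp,
                 anterior_anchor = if (!is.null(anchors)) anchors$anterior_anchor else curve[1, ],
                 posterior_anchor = if (!is.null(anchors)) anchors$posterior_anchor else curve[nrow(curve), ],
                 extension_points = rbind(ext_a_pt, ext_p_pt),
                 polyline = poly, position = position,
                 terminus = terminus, on_extension = on_ext,
                 n_polyline = n_polyline, extension_frac = extension_frac),
            class = "ap_axis")
}

#' @export
print.ap_axis <- function(x, ...) {
  cat("Reconstructed AP axis\n")
  cat("  control points :", nrow(x$control_points), "\n")
  cat("  polyline points:", x$n_polyline, "\n")
  cat(sprintf("  termini at arc positions %.3f (anterior), %.3f (posterior)\n",
              x$terminus[1], x$terminus[2]))
  cat(sprintf("  terminus-to-terminus length %.3f embedding units\n",
              diff(x$terminus)))
  invisible(x)
}

#' @export
plot.ap_axis <- function(x, emb = NULL, ...) {
  if (!is.null(emb))
    graphics::plot(emb$x, emb$y, pch = 16, cex = 0.3, col = "grey70",
                   xlab = "x", ylab = "y", ...)
  else
    graphics::plot(x$polyline, type = "n", xlab = "x", ylab = "y", ...)
  graphics::lines(x$polyline[!x$on_extension, ], col = "firebrick", lwd = 2)
  graphics::lines(x$polyline[x$position < x$terminus[1], , drop = FALSE],
                  col = "grey40", lty = 2)
  graphics::lines(x$polyline[x$position > x$terminus[2], , drop = FALSE],
                  col = "grey40", lty = 2)
  graphics::points(x$control_points, pch = 4, col = "navy")
  invisible(x)
}

#' Assign each nucleus an arc-length position and distance on the axis
#'
#' Finds the exact nearest of the polyline points for each nucleus in the axis
#' clusters; its arc-length position becomes the nucleus position and the
#' Euclidean distance to it the nucleus distance. Nuclei whose nearest point
#' lies on an extension segment (i.e. more anterior or posterior than the
#' spline termini) are omitted. Optionally, nuclei near the anterior end that
#' do not express a required marker set are also omitted.
#'
#' @param emb embedding table.
#' @param curve an \code{ap_axis} built from the same embedding.
#' @param axis_clusters cluster labels to position.
#' @param anterior_exclusion optional list(genes=, nm=, frac=): drop nuclei in
#'   the anterior \code{frac} of the axis that express none of \code{genes}.
#' @return data frame (nucleus_id, position, distance) with attribute
#'   \code{terminus}; omitted nuclei are absent.
#' @export
assign_positions <- function(emb, curve, axis_clusters,
                             anterior_exclusion = NULL) {
  if (!length(axis_clusters)) stop("axis_clusters must be non-empty")
  sel <- emb$cluster %in% axis_clusters
  if (!any(sel)) stop("no nuclei in the given axis clusters")
  ids <- emb$nucleus_id[sel]
  pts <- cbind(emb$x[sel], emb$y[sel])
  idx <- nearest_point_index(pts, curve$polyline)
  pos <- curve$position[idx]
  dist <- sqrt(rowSums((pts - curve$polyline[idx, , drop = FALSE])^2))
  keep <- !curve$on_extension[idx]
  out <- data.frame(nucleus_id = ids[keep], position = pos[keep],
                    distance = dist[keep], stringsAsFactors = FALSE)
  if (!is.null(anterior_exclusion)) {
    ae <- anterior_exclusion
    frac <- if (is.null(ae$frac)) 0.1 else ae$frac
    lim <- curve$terminus[1] + frac * diff(curve$terminus)
    genes <- intersect(ae$genes, rownames(ae$nm))
    expr <- Matrix::colSums(ae$nm[genes, out$nucleus_id, drop = FALSE]) > 0
    out <- out[!(out$position < lim & !expr), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "terminus") <- curve$terminus
  out
}
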