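#' Smoothing parameters for axis expression profiles
#'
#' @param near_axis_threshold maximum nucleus-to-curve distance (embedding
#'   units, inclusive) for a nucleus to contribute to profiles. The default
#'   0.3 is calibrated to the scale of the embeddings the method was developed
#'   on and must be re-tuned for embeddings on other scales.
#' @param span loess span as a fraction of the (doubled) points.
#' @param grid_size number of evenly spaced evaluation points over the
#'   mirrored range (default 160).
#' @param trim_window indices of the grid kept and re-indexed 1..grid_size/2
#'   (default 41:120, the central half covering the original axis).
#' @param min_points minimum doubled points required for smoothing.
#' @return a \code{smoothing_params} list.
#' @export
smoothing_params <- function(near_axis_threshold = 0.3, span = 0.05,
                             grid_size = 160,
                             trim_window = (grid_size / 4 + 1):(grid_size * 3 / 4),
                             min_points = 30) {
  stopifnot(span > 0, span <= 1, grid_size >= 4)
  if (length(trim_window) != grid_size / 2)
    stop("trim_window length must equal grid_size / 2")
  structure(list(near_axis_threshold = near_axis_threshold, span = span,
                 grid_size = grid_size, trim_window = trim_window,
                 min_points = min_points), class = "smoothing_params")
}

#' Select nuclei near the axis curve
#'
#' Keeps nuclei with distance <= threshold ("within" is inclusive), preserving
#' order.
#'
#' @param pos nucleus position table from \code{assign_positions}.
#' @param threshold distance threshold in embedding units.
#' @return filtered position table (terminus attribute preserved).
#' @export
select_near_axis <- function(pos, threshold = 0.3) {
  keep <- pos$distance <= threshold
  if (!any(keep))
    stop("no nuclei within ", threshold, " of the axis (", nrow(pos),
         " positioned nuclei; min distance ", round(min(pos$distance), 3), ")")
  out <- pos[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "terminus") <- attr(pos, "terminus")
  out
}

#' Mirror nucleus positions at both termini
#'
#' Appends to each nucleus a mirrored copy: nuclei in the anterior half
#' (position <= midpoint of the termini) are reflected at the anterior
#' terminus, those in the posterior half at the posterior terminus. The output
#' has exactly twice the rows and spans [2a - c, 2b - c] where a, b are the
#' termini and c their midpoint. Mirroring suppresses the boundary bias of the
#' subsequent local regression at the axis ends.
#'
#' @param pos position table with a \code{terminus} attribute (or pass
#'   \code{terminus} explicitly).
#' @param terminus length-2 numeric c(anterior, posterior).
#' @return doubled position table with a logical \code{mirrored} column.
#' @export
mirror_positions <- function(pos, terminus = attr(pos, "terminus")) {
  if (is.null(terminus)) stop("terminus positions required")
  a <- terminus[1]; b <- terminus[2]; cc <- (a + b) / 2
  anterior <- pos$position <= cc
  mir <- pos
  mir$position <- ifelse(anterior, 2 * a - pos$position, 2 * b - pos$position)
  pos$mirrored <- FALSE
  mir$mirrored <- TRUE
  out <- rbind(pos, mir)
  rownames(out) <- NULL
  attr(out, "terminus") <- terminus
  out
}

#' Smooth one gene's expression along the mirrored axis
#'
#' Loess (local quadratic, tricube weights, gaussian family) of expression
#' against doubled position, evaluated at \code{grid_size} evenly spaced points
#' spanning the mirrored range; the central trim window is kept and re-indexed
#' 1..grid_size/2 (anterior to posterior).
#'
#' @param doubled doubled position table from \code{mirror_positions}.
#' @param values expression value per doubled row (same order).
#' @param params \code{smoothing_params}.
#' @return numeric profile of length grid_size/2.
#' @export
smooth_profile <- function(doubled, values, params = smoothing_params()) {
  if (nrow(doubled) < params$min_points)
    stop("need >= ", params$min_points, " doubled points")
  p <- doubled$position
  if (diff(range(p)) == 0) stop("degenerate positions (all identical)")
  term <- attr(doubled, "terminus")
  a <- term[1]; b <- term[2]; cc <- (a + b) / 2
  grid <- seq(2 * a - cc, 2 * b - cc, length.out = params$grid_size)
  fit <- stats::loess(values ~ p, span = params$span, degree = 2,
                      family = "gaussian")
  out <- stats::predict(fit, data.frame(p = grid))
  unname(out[params$trim_window])
}

#' Build the full gene x 80-position profile matrix
#'
#' Selects nuclei within the near-axis threshold, mirrors their positions at
#' the termini, and loess-smooths every gene's log-normalized expression into a
#' profile at grid_size/2 subdivisions (default 80) of the reconstructed axis.
#' Genes without expression among the selected nuclei get all-zero profiles.
#'
#' @param nm normalized gene x nucleus matrix.
#' @param pos nucleus position table (with terminus attribute).
#' @param params \code{smoothing_params}.
#' @return matrix genes x subdivisions (columns P1..Pk, anterior to posterior)
#'   with attribute \code{params}.
#' @export
build_profile_matrix <- function(nm, pos, params = smoothing_params()) {
  if (!all(pos$nucleus_id %in% colnames(nm)))
    stop("position table contains nucleus IDs absent from the matrix")
  near <- select_near_axis(pos, params$near_axis_threshold)
  doubled <- mirror_positions(near)
  X <- as.matrix(nm[, near$nucleus_id, drop = FALSE])
  Xd <- X[, c(seq_len(nrow(near)), seq_len(nrow(near))), drop = FALSE]
  k <- length(params$trim_window)
  prof <- matrix(0, nrow = nrow(nm), ncol = k,
                 dimnames = list(rownames(nm), paste0("P", seq_len(k))))
  nonzero <- which(rowSums(Xd != 0) > 0)
  for (g in nonzero)
    prof[g, ] <- smooth_profile(doubled, Xd[g, ], params)
  attr(prof, "params") <- params
  prof
}

#' Write / read profile matrices as CSV
#'
#' Rows are genes, columns the axis subdivisions P1..Pk.
#'
#' @param prof profile matrix.
#' @param path CSV path.
#' @return path (write) or matrix (read).
#' @export
write_profiles <- function(prof, path) {
  df <- data.frame(gene_id = rownames(prof), prof, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
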