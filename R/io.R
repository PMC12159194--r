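#' QC threshold presets
#'
#' Stage-specific cell/nucleus filtering presets: a barcode is retained when it
#' has strictly more than \code{min_genes} detected genes (count > 0) and
#' strictly fewer than \code{max_molecules} total molecules.
#'
#' @format named list of \code{c(min_genes, max_molecules)} pairs.
#' @export
qc_presets <- list(
  stage7_cell        = c(min_genes = 1500, max_molecules = 20000),
  stage7_nucleus     = c(min_genes = 2000, max_molecules = 20000),
  latestage5_nucleus = c(min_genes = 1500, max_molecules = 15000))

validate_count_matrix <- function(m, where = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(where, ": gene and barcode names required")
  if (anyDuplicated(rownames(m)))
    stop(where, ": duplicate gene IDs (e.g. '",
         rownames(m)[duplicated(rownames(m))][1], "')")
  if (anyDuplicated(colnames(m)))
    stop(where, ": duplicate barcodes (e.g. '",
         colnames(m)[duplicated(colnames(m))][1], "')")
  x <- m@x
  if (length(x)) {
    if (any(x < 0)) stop(where, ": negative counts")
    if (any(x != round(x))) stop(where, ": non-integer counts")
  }
  invisible(m)
}

#' Read a gene x nucleus count matrix
#'
#' Reads either a 10x-style MatrixMarket triplet layout (directory holding
#' \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}) or a dense CSV
#' (first column gene ids, header barcodes). The result round-trips bit-exactly
#' with \code{write_count_matrix}.
#'
#' @param path directory (mtx_triplet) or file (dense_csv).
#' @param dialect "mtx_triplet" or "dense_csv".
#' @return sparse dgCMatrix with gene rownames and barcode colnames.
#' @export
read_count_matrix <- function(path, dialect = c("mtx_triplet", "dense_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    ftsv <- file.path(path, "features.tsv")
    btsv <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, ftsv, btsv))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("malformed MatrixMarket file ", mtx,
                                           ": ", conditionMessage(e)))
    genes <- readLines(ftsv)
    genes <- vapply(strsplit(genes, "\t"), `[[`, "", 1L)
    bcs <- readLines(btsv)
    if (nrow(m) != length(genes))
      stop("dimension mismatch in ", path, ": matrix has ", nrow(m),
           " rows but features.tsv has ", length(genes))
    if (ncol(m) != length(bcs))
      stop("dimension mismatch in ", path, ": matrix has ", ncol(m),
           " columns but barcodes.tsv has ", length(bcs))
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, bcs)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  }
  m <- Matrix::drop0(m)
  validate_count_matrix(m, where = paste0("'", path, "'"))
  m
}

#' Write a count matrix as MatrixMarket triplets
#'
#' @param m sparse gene x nucleus matrix.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Filter low-quality barcodes by detected genes and total molecules
#'
#' Keeps barcodes with strictly more than \code{min_genes} genes detected
#' (count > 0) and strictly fewer than \code{max_molecules} total molecules,
#' matching the "more than" / "fewer than" convention of stage presets (see
#' \code{\link{qc_presets}}).
#'
#' @param m count matrix.
#' @param min_genes,max_molecules positive thresholds (strict).
#' @param preset optional preset name overriding the two thresholds.
#' @return list with \code{matrix} (retained columns) and \code{report}
#'   (data frame of removed barcodes with the criterion that failed).
#' @export
qc_filter <- function(m, min_genes = 2000, max_molecules = 20000,
                      preset = NULL) {
  if (!is.null(preset)) {
    p <- qc_presets[[match.arg(preset, names(qc_presets))]]
    min_genes <- p[["min_genes"]]; max_molecules <- p[["max_molecules"]]
  }
  if (ncol(m) == 0) stop("empty count matrix")
  if (min_genes <= 0 || max_molecules <= 0) stop("thresholds must be positive")
  m <- Matrix::drop0(m)
  n_genes <- diff(m@p)
  n_mol <- Matrix::colSums(m)
  keep <- n_genes > min_genes & n_mol < max_molecules
  reason <- character(sum(!keep))
  low <- n_genes[!keep] <= min_genes
  high <- n_mol[!keep] >= max_molecules
  reason[low & !high] <- "too_few_genes"
  reason[!low & high] <- "too_many_molecules"
  reason[low & high] <- "too_few_genes;too_many_molecules"
  report <- data.frame(barcode = colnames(m)[!keep],
                       n_genes = n_genes[!keep], n_molecules = n_mol[!keep],
                       reason = reason, stringsAsFactors = FALSE)
  list(matrix = m[, keep, drop = FALSE], report = report)
}

#' Log-normalize a count matrix
#'
#' value = ln(1 + count * scale_factor / column_total). The sparsity pattern is
#' preserved (zero count gives zero value) and values within a nucleus are
#' monotone in count.
#'
#' @param m count matrix; every column must have total count > 0.
#' @param scale_factor positive scale (default 10,000, the convention of the
#'   single-cell clustering toolkits).
#' @return sparse normalized matrix with the same dimnames.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  if (scale_factor <= 0) stop("scale_factor must be positive")
  m <- Matrix::drop0(m)
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("zero-total column(s): ",
         paste(utils::head(colnames(m)[tot == 0], 3), collapse = ", "),
         " (QC should have removed them)")
  nm <- m
  nm@x <- log1p(m@x * scale_factor / rep.int(tot, diff(m@p)))
  nm
}
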