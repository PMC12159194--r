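#' Stripe-pattern specification for one simulated gene
#'
#' Describes the latent-axis mean function of a simulated gene in the germ-band
#' simulator. The mean expression of gene \eqn{g} in nucleus \eqn{i} is
#' \eqn{s_i \lambda_g(u_i)} where \eqn{u_i \in [0,1]} is the nucleus' latent
#' anterior-posterior position and \eqn{s_i} its library-size factor.
#'
#' Pattern classes:
#' \describe{
#'   \item{bi_split / tri_split / regional_block / terminal_anchor_A /
#'     terminal_anchor_P}{sum of Gaussian bumps of width \code{peak_width}
#'     centred at \code{peak_centers} (anchors are pinned to u = 0 / u = 1).}
#'   \item{anterior_gradient / posterior_gradient}{a single wide bump pinned to
#'     the respective terminus, i.e. a monotone gradient over most of the axis.}
#'   \item{oscillatory}{\code{baseline + amplitude * max(0, cos(2*pi*(u - phase)
#'     / period))^exponent}, restricted to a posterior window; the window is
#'     carried in \code{peak_centers} as \code{c(start, end)} (default
#'     \code{c(0.5, 1)}). The squared cosine (\code{exponent = 2}) gives
#'     distinct peak and trough phases, as seen for antiphase segmentation
#'     oscillators.}
#'   \item{uniform}{constant \code{baseline + amplitude}.}
#'   \item{sparse_noise}{expressed in a random \code{sparse_fraction} of nuclei,
#'     independent of position.}
#' }
#'
#' @param gene_id character gene identifier.
#' @param pattern_class one of the classes listed above.
#' @param peak_centers numeric vector of latent positions in [0,1]
#'   (bi_split needs exactly 2, tri_split exactly 3; oscillatory uses it as the
#'   active window).
#' @param peak_width Gaussian bump s.d. in latent-axis units.
#' @param period,phase oscillatory period and phase in latent-axis units.
#' @param amplitude,baseline mean-count scale (>= 0).
#' @param dispersion negative-binomial size parameter (> 0); \code{Inf} gives
#'   Poisson counts.
#' @param sparse_fraction fraction of expressing nuclei (sparse_noise only).
#' @param exponent cosine-bump exponent for oscillatory genes.
#' @return an object of class \code{stripe_spec}.
#' @export
stripe_spec <- function(gene_id, pattern_class, peak_centers = numeric(),
                        peak_width = 0.03, period = NA_real_, phase = 0,
                        amplitude = 8, baseline = 0.05, dispersion = 10,
                        sparse_fraction = NA_real_, exponent = 2) {
  classes <- c("anterior_gradient", "posterior_gradient", "regional_block",
               "bi_split", "tri_split", "oscillatory", "terminal_anchor_A",
               "terminal_anchor_P", "uniform", "sparse_noise")
  pattern_class <- match.arg(pattern_class, classes)
  spec <- structure(list(
    gene_id = as.character(gene_id), pattern_class = pattern_class,
    peak_centers = as.numeric(peak_centers), peak_width = peak_width,
    period = period, phase = phase, amplitude = amplitude,
    baseline = baseline, dispersion = dispersion,
    sparse_fraction = sparse_fraction, exponent = exponent),
    class = "stripe_spec")
  validate_stripe_spec(spec)
  spec
}

validate_stripe_spec <- function(spec) {
  fail <- function(msg) stop("invalid stripe_spec for gene '", spec$gene_id,
                             "': ", msg, call. = FALSE)
  if (!nzchar(spec$gene_id)) fail("empty gene_id")
  if (length(spec$peak_centers) &&
      (any(spec$peak_centers < 0) || any(spec$peak_centers > 1)))
    fail("peak_centers must lie in [0,1]")
  if (spec$pattern_class == "bi_split" && length(spec$peak_centers) != 2L)
    fail("bi_split requires exactly 2 peak_centers")
  if (spec$pattern_class == "tri_split" && length(spec$peak_centers) != 3L)
    fail("tri_split requires exactly 3 peak_centers")
  if (spec$pattern_class == "oscillatory" &&
      (!is.finite(spec$period) || spec$period <= 0))
    fail("oscillatory requires period > 0")
  if (spec$amplitude < 0 || spec$baseline < 0)
    fail("amplitude and baseline must be >= 0")
  if (spec$pattern_class != "sparse_noise" &&
      spec$amplitude + spec$baseline <= 0 &&
      spec$pattern_class != "uniform")
    fail("amplitude + baseline must be > 0")
  if (!is.na(spec$dispersion) && spec$dispersion <= 0)
    fail("dispersion must be > 0")
  if (spec$pattern_class == "sparse_noise" &&
      (is.na(spec$sparse_fraction) || spec$sparse_fraction < 0 ||
       spec$sparse_fraction > 1))
    fail("sparse_noise requires sparse_fraction in [0,1]")
  invisible(spec)
}

#' Latent-axis mean function of a stripe spec
#'
#' @param spec a \code{stripe_spec}.
#' @param u vector of latent positions in [0,1].
#' @return vector of mean expression values \eqn{\lambda(u)}.
#' @export
stripe_mean <- function(spec, u) {
  bumps <- function(centers, width) {
    if (!length(centers)) return(rep(0, length(u)))
    rowSums(vapply(centers, function(cc) exp(-(u - cc)^2 / (2 * width^2)),
                   numeric(length(u))))
  }
  lam <- switch(spec$pattern_class,
    anterior_gradient  = bumps(0, max(spec$peak_width, 0.3)),
    posterior_gradient = bumps(1, max(spec$peak_width, 0.3)),
    regional_block     = ,
    bi_split           = ,
    tri_split          = bumps(spec$peak_centers, spec$peak_width),
    terminal_anchor_A  = bumps(0, spec$peak_width),
    terminal_anchor_P  = bumps(1, spec$peak_width),
    oscillatory = {
      win <- if (length(spec$peak_centers) >= 2) spec$peak_centers[1:2] else c(0.5, 1)
      co <- cos(2 * pi * (u - spec$phase) / spec$period)
      pmax(co, 0)^spec$exponent * (u >= win[1] & u <= win[2])
    },
    uniform = rep(1, length(u)),
    sparse_noise = rep(1, length(u)))
  spec$baseline + spec$amplitude * lam
}

#' Default simulated gene panel
#'
#' A panel emulating the statistical structure of the segmenting germ band:
#' 40 patterned genes (8 bi-splitting genes arranged as 4 complementary pairs,
#' 6 tri-splitting, 10 oscillatory in two antiphase classes, 8 regional,
#' 4 terminal anchors, 4 gradients), 400 uniformly expressed genes and 60
#' sparsely expressed noise genes.
#'
#' @param n_uniform,n_sparse panel sizes for the unpatterned compartments.
#' @param seed integer seed controlling the randomized per-gene baselines and
#'   sparse fractions.
#' @return list of \code{stripe_spec} objects.
#' @export
default_gene_panel <- function(n_uniform = 400, n_sparse = 60, seed = 1L) {
  set.seed(seed)
  panel <- list()
  add <- function(s) panel[[length(panel) + 1L]] <<- s

  ## 4 complementary bi-splitting pairs in the head (hh-like / msx1-like)
  starts <- c(0.08, 0.13, 0.18, 0.23)
  for (j in seq_along(starts)) {
    add(stripe_spec(sprintf("bi_a_%d", j), "bi_split",
                    peak_centers = c(starts[j], starts[j] + 0.10)))
    add(stripe_spec(sprintf("bi_b_%d", j), "bi_split",
                    peak_centers = c(starts[j] + 0.05, starts[j] + 0.15)))
  }
  ## 6 tri-splitting genes in the thorax
  for (j in 1:6)
    add(stripe_spec(sprintf("tri_%d", j), "tri_split",
                    peak_centers = 0.33 + 0.01 * (j - 1) + c(0, 0.10, 0.20)))
  ## 10 oscillatory genes, two antiphase classes, period 0.15
  for (j in 1:5)
    add(stripe_spec(sprintf("osc_a_%d", j), "oscillatory",
                    peak_centers = c(0.5, 1), period = 0.15, phase = 0))
  for (j in 1:5)
    add(stripe_spec(sprintf("osc_b_%d", j), "oscillatory",
                    peak_centers = c(0.5, 1), period = 0.15, phase = 0.075))
  ## 8 regional genes (head / thorax / opisthosoma blocks)
  centers <- rep(c(0.15, 0.45, 0.72), length.out = 8)
  for (j in 1:8)
    add(stripe_spec(sprintf("reg_%d", j), "regional_block",
                    peak_centers = centers[j], peak_width = 0.10))
  ## 4 terminal anchors (six3-like anterior, prd2-like posterior)
  add(stripe_spec("anchor_A_1", "terminal_anchor_A", peak_width = 0.05, amplitude = 10))
  add(stripe_spec("anchor_A_2", "terminal_anchor_A", peak_width = 0.05, amplitude = 10))
  add(stripe_spec("anchor_P_1", "terminal_anchor_P", peak_width = 0.05, amplitude = 10))
  add(stripe_spec("anchor_P_2", "terminal_anchor_P", peak_width = 0.05, amplitude = 10))
  ## 4 gradients
  add(stripe_spec("grad_A_1", "anterior_gradient", amplitude = 6))
  add(stripe_spec("grad_A_2", "anterior_gradient", amplitude = 6))
  add(stripe_spec("grad_P_1", "posterior_gradient", amplitude = 6))
  add(stripe_spec("grad_P_2", "posterior_gradient", amplitude = 6))
  ## uniform housekeeping genes with lognormal baselines
  bl <- stats::rlnorm(n_uniform, meanlog = log(4), sdlog = 0.6)
  for (j in seq_len(n_uniform))
    add(stripe_spec(sprintf("uni_%03d", j), "uniform",
                    amplitude = 0, baseline = bl[j]))
  ## sparsely expressed noise genes: detected in at most a couple of nuclei,
  ## the regime the minimum-expression-gap filter is built to remove
  sf <- stats::runif(n_sparse, 0.00002, 0.0002)
  for (j in seq_len(n_sparse))
    add(stripe_spec(sprintf("sparse_%02d", j), "sparse_noise",
                    amplitude = 5, baseline = 0, sparse_fraction = sf[j]))
  panel
}

#' Simulate a germ-band count matrix with known ground truth
#'
#' Draws negative-binomial counts for a panel of genes over ectoderm nuclei
#' whose latent anterior-posterior positions u are uniform on [0,1], plus an
#' optional compartment of non-axial ("other") nuclei carrying a distinct
#' program (dedicated marker genes, no patterned expression). Library-size
#' factors are lognormal.
#'
#' @param n_ectoderm number of ectoderm nuclei (>= 10).
#' @param n_other number of non-axial nuclei.
#' @param gene_panel list of \code{stripe_spec} objects.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param lib_size_sdlog lognormal sdlog of library-size factors; 0 fixes all
#'   factors to 1.
#' @param n_other_markers dedicated marker genes added for the "other"
#'   compartment when \code{n_other > 0}.
#' @return list with elements \code{counts} (sparse gene x nucleus integer
#'   matrix) and \code{truth} (class \code{ap_truth}: per-nucleus data frame
#'   with \code{nucleus_id}, latent \code{u}, \code{tissue},
#'   \code{library_size}, plus the panel and seed).
#' @export
simulate_embryo <- function(n_ectoderm, n_other = 0, gene_panel, seed = 1L,
                            lib_size_sdlog = 0.35, n_other_markers = 10) {
  if (n_ectoderm < 10) stop("n_ectoderm must be >= 10")
  if (!length(gene_panel)) stop("gene_panel must be non-empty")
  lapply(gene_panel, validate_stripe_spec)
  ids <- vapply(gene_panel, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in panel: ", ids[duplicated(ids)][1])

  set.seed(seed)
  n <- n_ectoderm + n_other
  u <- stats::runif(n_ectoderm)
  s <- stats::rlnorm(n, meanlog = 0, sdlog = lib_size_sdlog)
  tissue <- rep(c("ectoderm", "other"), c(n_ectoderm, n_other))
  barcodes <- sprintf("nuc_%05d", seq_len(n))

  draw <- function(mu, size) {
    cnt <- numeric(length(mu))
    pos <- mu > 0
    if (any(pos)) {
      cnt[pos] <- if (is.infinite(size)) stats::rpois(sum(pos), mu[pos])
                  else stats::rnbinom(sum(pos), mu = mu[pos], size = size)
    }
    cnt
  }

  rows <- vector("list", length(gene_panel))
  for (g in seq_along(gene_panel)) {
    spec <- gene_panel[[g]]
    lam <- numeric(n)
    if (spec$pattern_class == "uniform") {
      lam[] <- stripe_mean(spec, 0.5)  # constant; other nuclei share it
    } else if (spec$pattern_class == "sparse_noise") {
      n_expr <- stats::rbinom(1, n, spec$sparse_fraction)
      on <- sample.int(n, n_expr)
      lam[on] <- spec$baseline + spec$amplitude
    } else {
      lam[seq_len(n_ectoderm)] <- stripe_mean(spec, u)
      if (n_other > 0) lam[(n_ectoderm + 1):n] <- spec$baseline
    }
    rows[[g]] <- draw(s * lam, spec$dispersion)
  }
  gene_ids <- ids
  if (n_other > 0 && n_other_markers > 0) {
    for (j in seq_len(n_other_markers)) {
      lam <- numeric(n)
      lam[(n_ectoderm + 1):n] <- 10
      rows[[length(rows) + 1L]] <- draw(s * lam, 10)
      gene_ids <- c(gene_ids, sprintf("other_marker_%02d", j))
    }
  }
  counts <- Matrix::Matrix(do.call(rbind, rows), sparse = TRUE)
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(gene_ids, barcodes)

  truth <- structure(list(
    nuclei = data.frame(nucleus_id = barcodes,
                        u = c(u, rep(NA_real_, n_other)),
                        tissue = tissue, library_size = s,
                        stringsAsFactors = FALSE),
    panel = gene_panel, seed = seed), class = "ap_truth")
  list(counts = counts, truth = truth)
}

#' Gene ids of a panel by pattern compartment
#'
#' Convenience accessor used by recovery tests: classifies panel genes into
#' \code{patterned}, \code{uniform} and \code{sparse} compartments.
#'
#' @param gene_panel list of \code{stripe_spec}s.
#' @return named list of character vectors.
#' @export
panel_gene_sets <- function(gene_panel) {
  cls <- vapply(gene_panel, `[[`, "", "pattern_class")
  ids <- vapply(gene_panel, `[[`, "", "gene_id")
  list(patterned = ids[!cls %in% c("uniform", "sparse_noise")],
       uniform = ids[cls == "uniform"],
       sparse = ids[cls == "sparse_noise"],
       oscillatory = ids[cls == "oscillatory"],
       anchors_anterior = ids[cls == "terminal_anchor_A"],
       anchors_posterior = ids[cls == "terminal_anchor_P"])
}

#' Embed simulated ground truth as a noisy planar curve
#'
#' Maps each ectoderm nucleus to a point on a parametric planar curve of total
#' length ~10 embedding units (a straight line, a semicircular arc, or an
#' S-shaped curve) at its latent position u, plus isotropic Gaussian noise.
#' Non-axial nuclei are placed in a separate blob. Cluster labels are assigned
#' by binning u into equal-width bins, emulating the axially aligned ectoderm
#' clusters of a graph-clustering run.
#'
#' @param truth an \code{ap_truth} object.
#' @param curve_shape "line", "arc" or "s_curve".
#' @param noise_sd isotropic Gaussian noise s.d. in embedding units.
#' @param seed integer seed.
#' @param n_bins number of equal-width u bins for cluster labels.
#' @return data frame (nucleus_id, x, y, cluster) with attributes
#'   \code{curve_shape}, \code{curve_length} and \code{arc_radius} (arc only).
#' @export
embed_ground_truth <- function(truth, curve_shape = c("arc", "line", "s_curve"),
                               noise_sd = 0, seed = 1L, n_bins = 10) {
  curve_shape <- match.arg(curve_shape)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  nuc <- truth$nuclei
  ect <- nuc$tissue == "ectoderm"
  if (!any(ect)) stop("truth has no ectoderm nuclei")
  u <- nuc$u[ect]

  gamma <- switch(curve_shape,
    line = function(u) cbind(10 * u, 0 * u),
    arc = {
      R <- 10 / pi
      function(u) cbind(R * cos(pi * (1 - u)), R * sin(pi * (1 - u)))
    },
    s_curve = function(u) cbind(8 * u, 1.5 * sin(2 * pi * u)))
  set.seed(seed)
  xy <- gamma(u)
  xy <- xy + matrix(stats::rnorm(2 * nrow(xy), 0, noise_sd), ncol = 2)
  cl <- paste0("ecto_", pmin(n_bins, floor(u * n_bins) + 1L))

  n_other <- sum(!ect)
  if (n_other > 0) {
    ctr <- c(mean(range(xy[, 1])), min(xy[, 2]) - 4)
    oxy <- cbind(stats::rnorm(n_other, ctr[1], 0.5),
                 stats::rnorm(n_other, ctr[2], 0.5))
    xy <- rbind(xy, oxy)
    cl <- c(cl, rep("other", n_other))
  }
  out <- data.frame(nucleus_id = c(nuc$nucleus_id[ect], nuc$nucleus_id[!ect]),
                    x = xy[, 1], y = xy[, 2], cluster = cl,
                    stringsAsFactors = FALSE)
  ## restore original nucleus order
  out <- out[match(nuc$nucleus_id, out$nucleus_id), ]
  rownames(out) <- NULL
  attr(out, "curve_shape") <- curve_shape
  attr(out, "curve_length") <- switch(curve_shape, line = 10, arc = 10,
                                      s_curve = curve_arc_length(gamma))
  if (curve_shape == "arc") attr(out, "arc_radius") <- 10 / pi
  out
}

curve_arc_length <- function(gamma, n = 2000) {
  p <- gamma(seq(0, 1, length.out = n))
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Write a simulated dataset to disk
#'
#' Writes the count matrix as MatrixMarket triplets with feature and barcode
#' tables, the ground truth as JSON (sidecar, so any stage can be scored
#' without re-simulation) and the embedding as TSV.
#'
#' @param sim result of \code{simulate_embryo}.
#' @param emb optional embedding table from \code{embed_ground_truth}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, emb = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, dir)
  truth <- sim$truth
  jsonlite::write_json(
    list(nuclei = truth$nuclei, seed = truth$seed,
         panel = lapply(truth$panel, unclass)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(emb))
    utils::write.table(emb, file.path(dir, "embedding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
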