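#' Pipeline configuration
#'
#' Builds the nested configuration driving \code{\link{run_pipeline}}. Every
#' random operation carries an explicit seed; the config round-trips through
#' YAML unchanged (\code{read_config} / \code{write_config}). Unknown keys are
#' errors, protecting against silent typos in thresholds.
#'
#' @param simulate list(n_ectoderm, n_other, seed, noise_sd, curve_shape):
#'   synthetic-input directive (NULL to supply a count matrix instead).
#' @param qc list(min_genes, max_molecules) or list(preset = name).
#' @param clustering list(n_variable, n_dims, resolution, seed, algorithm).
#' @param axis list(n_polyline, anchor_anterior, anchor_posterior,
#'   manual_points, near_axis_threshold).
#' @param smoothing list(span, grid_size).
#' @param selection list(k1, k2_range, rule, whitelist).
#' @param analysis list(regions, max_threshold, derivative_top_k).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(simulate = list(), qc = list(), clustering = list(),
                            axis = list(), smoothing = list(),
                            selection = list(), analysis = list()) {
  defaults <- list(
    simulate = list(n_ectoderm = 3000, n_other = 400, seed = 1L,
                    curve_shape = "arc", noise_sd = 0.5),
    qc = list(min_genes = 0, max_molecules = Inf, preset = NULL),
    clustering = list(n_variable = 2000, n_dims = 50, resolution = 0.5,
                      seed = 1L, algorithm = "leiden"),
    axis = list(n_polyline = 10000, anchor_anterior = NULL,
                anchor_posterior = NULL, manual_points = NULL,
                near_axis_threshold = NULL, use_truth_embedding = FALSE),
    smoothing = list(span = 0.05, grid_size = 160),
    selection = list(k1 = 12, k2_range = 2:5, rule = "median_mad",
                     whitelist = NULL),
    analysis = list(regions = list(A = c(1, 33), B = c(28, 58), C = c(55, 80)),
                    max_threshold = 0.2, derivative_top_k = 50))
  user <- list(simulate = simulate, qc = qc, clustering = clustering,
               axis = axis, smoothing = smoothing, selection = selection,
               analysis = analysis)
  cfg <- defaults
  for (sec in names(user)) {
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      stop("unknown config key(s) in '", sec, "': ",
           paste(unknown, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> QC -> normalize -> cluster/embed -> axis
#' reconstruction -> profiles -> selection -> derivatives, returning all stage
#' outputs plus a manifest of seeds and row/column counts. When the input is a
#' synthetic directive, the generator's own embedding and cluster labels can be
#' used in place of the clustering stage (\code{axis$use_truth_embedding}),
#' which decouples axis-reconstruction validation from embedding stochasticity.
#'
#' @param config a \code{pipeline_config}.
#' @param counts optional gene x nucleus count matrix (overrides the simulate
#'   directive).
#' @param outdir optional directory to write stage outputs into.
#' @return list with counts, truth (synthetic only), qc report, normalized
#'   matrix, embedding, axis curve, positions, profiles, derivatives,
#'   selection, and manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), counts = NULL,
                         outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL; emb_truth <- NULL
  if (is.null(counts)) {
    sim_cfg <- config$simulate
    sim <- stage("simulate", {
      panel <- default_gene_panel(seed = sim_cfg$seed)
      simulate_embryo(sim_cfg$n_ectoderm, sim_cfg$n_other, panel,
                      seed = sim_cfg$seed)
    })
    counts <- sim$counts
    truth <- sim$truth
    emb_truth <- stage("embed", embed_ground_truth(
      truth, curve_shape = sim_cfg$curve_shape, noise_sd = sim_cfg$noise_sd,
      seed = sim_cfg$seed))
  }

  qc <- stage("qc", {
    q <- config$qc
    if (!is.null(q$preset)) qc_filter(counts, preset = q$preset)
    else if (q$min_genes > 0 || is.finite(q$max_molecules))
      qc_filter(counts, q$min_genes, q$max_molecules)
    else list(matrix = counts,
              report = data.frame(barcode = character(), n_genes = numeric(),
                                  n_molecules = numeric(), reason = character()))
  })
  nm <- stage("normalize", log_normalize(qc$matrix))

  if (isTRUE(config$axis$use_truth_embedding) && !is.null(emb_truth)) {
    emb <- emb_truth[emb_truth$nucleus_id %in% colnames(nm), , drop = FALSE]
  } else {
    cc <- config$clustering
    emb <- stage("cluster", reduce_and_cluster(
      nm, n_variable = cc$n_variable,
      n_dims = min(cc$n_dims, min(dim(nm)) - 1),
      resolution = cc$resolution, seed = cc$seed, algorithm = cc$algorithm))
  }
  axis_clusters <- setdiff(unique(as.character(emb$cluster)), "other")

  ax <- config$axis
  ## near-axis threshold: the conventional 0.3-unit value for supplied data; for
  ## synthetic runs, 3 x the embedding noise sd (covers ~99% of on-axis nuclei)
  if (is.null(ax$near_axis_threshold))
    ax$near_axis_threshold <- if (is.null(truth)) 0.3
                              else 3 * config$simulate$noise_sd
  anchor_genes <- if (!is.null(ax$anchor_anterior))
    list(anterior = ax$anchor_anterior, posterior = ax$anchor_posterior)
  else if (!is.null(truth)) {
    gs <- panel_gene_sets(truth$panel)
    list(anterior = gs$anchors_anterior, posterior = gs$anchors_posterior)
  } else NULL

  rcp <- stage("axis", extract_ridge_control_points(
    emb, axis_clusters, anchor_genes = anchor_genes, nm = nm,
    manual_points = ax$manual_points))
  curve <- stage("axis", fit_axis_curve(rcp$control_points, anchors = rcp,
                                        n_polyline = ax$n_polyline))
  pos <- stage("axis", assign_positions(emb, curve, axis_clusters))

  sp <- smoothing_params(near_axis_threshold = ax$near_axis_threshold,
                         span = config$smoothing$span,
                         grid_size = config$smoothing$grid_size)
  profiles <- stage("profiles", build_profile_matrix(nm, pos, sp))
  derivs <- stage("derive", first_derivative(profiles))

  sel_cfg <- config$selection
  sparse <- stage("select", sparse_gene_filter(nm, select_near_axis(
    pos, ax$near_axis_threshold)))
  feats <- stage("select", compute_pattern_features(
    profiles[sparse$retained, , drop = FALSE]))
  selection <- stage("select", two_round_select(
    feats, k1 = sel_cfg$k1, k2_range = sel_cfg$k2_range, rule = sel_cfg$rule,
    whitelist = sel_cfg$whitelist))
  selection$excluded_sparse <- FALSE
  if (length(sparse$excluded))
    selection <- rbind(selection,
      data.frame(gene_id = sparse$excluded, round1_group = NA_integer_,
                 round2_group = NA_integer_, selected = FALSE,
                 excluded_sparse = TRUE, stringsAsFactors = FALSE))

  manifest <- list(
    seeds = list(simulate = config$simulate$seed,
                 clustering = config$clustering$seed),
    counts_dim = dim(counts), qc_removed = nrow(qc$report),
    normalized_dim = dim(nm), n_clusters = length(unique(emb$cluster)),
    n_positioned = nrow(pos), profile_dim = dim(profiles),
    n_selected = sum(selection$selected),
    n_sparse_excluded = sum(selection$excluded_sparse))

  out <- list(counts = counts, truth = truth, qc_report = qc$report,
              normalized = nm, embedding = emb, curve = curve, positions = pos,
              profiles = profiles, derivatives = derivs, selection = selection,
              manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_profiles(profiles, file.path(outdir, "profiles.csv"))
    write_profiles(derivs, file.path(outdir, "derivatives.csv"))
    utils::write.table(pos, file.path(outdir, "positions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(selection, file.path(outdir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
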