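#' Pipeline configuration with the study's frozen defaults
#'
#' Collects every stage parameter in one list, defaulting to the values the
#' analysis was designed around: library-size floor 1000 UMIs,
#' mitochondrial ceiling 20%, complexity residual 0.1, fine QC clustering
#' k=8 with a 1e-10 Z-test cutoff, 3000 highly variable genes, PCA to 75%
#' variance, k=30 neighbor graphs, eigengap searched in the first 40
#' eigenvalues, imputation k=5/t=3, 500 trend bins, trend clustering k=20,
#' spatial selection at FDR 1e-5 and Z >= 10, module cuts at linkage
#' distances 10/6/4, and differential expression at FDR 0.001 with hurdle
#' effect 0.24 (0.10 for cross-region propagation).
#'
#' @param ... named overrides of any default
#' @return a \code{pipeline_config} list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_umis = 1000, max_mito = 0.20, complexity_resid = 0.1,
    qc_cluster_k = 8L, qc_z_cutoff = 1e-10,
    n_top_genes = 3000L, pca_target = 0.75, k_neighbors = 30L,
    eigengap_window = 40L, n_diffusion_components = 40L,
    impute_k = 5L, impute_t = 3L,
    trend_bins = 500L, trend_cluster_k = 20L,
    autocorr_fdr = 1e-5, autocorr_zmin = 10, autocorr_range_min = 1,
    cut_distances = c(10, 6, 4),
    de_fdr = 0.001, de_effect = 0.24, de_propagate_effect = 0.10,
    seed = 0L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the spatial-axis pipeline on a dataset
#'
#' Chains the core stages on an already-QCed dataset: normalization, HVG
#' selection, PCA, adaptive kNN graph, diffusion map with eigengap
#' selection, multiscale embedding, marker-guided identification of the AP
#' and ML components, local autocorrelation on the three latent spaces
#' (AP component alone, ML component alone, multiscale), spatial gene
#' selection, imputation, trend fitting and clustering along each axis
#' component, and the multiscale module hierarchy.
#'
#' @param ds a QC-passed \code{plate_dataset}
#' @param ap_markers,ml_markers [gene_set()]s anchoring the
#'   anterior-posterior and mediolateral axes (used only to identify which
#'   diffusion component carries each axis, never to select genes)
#' @param config a [pipeline_config()]
#' @return list of stage artifacts: embeddings, diffusion result, axis
#'   component matches, autocorrelation results and selections per space,
#'   trend sets, and the module hierarchy
#' @export
run_spatial_pipeline <- function(ds, ap_markers, ml_markers,
                                 config = pipeline_config()) {
  ds <- normalize_log(ds)
  hv <- select_hvg(ds, n_top = min(config$n_top_genes, ncol(ds$counts)))
  pca <- pca_to_variance(ds, hvg = hv, target = config$pca_target)
  g <- knn_graph(pca, k = config$k_neighbors, mode = "adaptive_gaussian")
  dr <- diffusion_map(g, n_components = config$n_diffusion_components)
  n_sel <- select_eigengap(dr$eigenvalues, config$eigengap_window)

  # The axis-carrying components are found by marker correlation over a
  # window of top components (never hard-coded indices); the multiscale
  # space must span at least the eigengap selection and both axis
  # components.
  window <- seq_len(min(10L, length(dr$eigenvalues)))
  emb_win <- dr$embedding
  emb_win$coordinates <- emb_win$coordinates[, window, drop = FALSE]
  ap_match <- match_axis_component(ds, emb_win, ap_markers)
  ml_cands <- setdiff(window, ap_match$index)
  ml_sub <- dr$embedding
  ml_sub$coordinates <- ml_sub$coordinates[, ml_cands, drop = FALSE]
  ml_match0 <- match_axis_component(ds, ml_sub, ml_markers)
  ml_match <- list(component = ml_match0$component,
                   index = ml_cands[ml_match0$index], r = ml_match0$r)

  ap_axis <- dr$embedding$coordinates[, ap_match$index]
  ml_axis <- dr$embedding$coordinates[, ml_match$index]
  ms <- multiscale_embed(dr, n = max(n_sel, ap_match$index, ml_match$index))

  spaces <- list(
    ap = matrix(ap_axis, ncol = 1),
    ml = matrix(ml_axis, ncol = 1),
    multiscale = ms$coordinates)
  autocorr <- lapply(names(spaces), function(nm)
    local_autocorrelation(ds, spaces[[nm]], k = config$k_neighbors,
                          space_tag = nm))
  names(autocorr) <- names(spaces)
  selections <- lapply(autocorr, select_spatial_genes,
                       fdr_max = config$autocorr_fdr,
                       z_min = config$autocorr_zmin,
                       range_min = config$autocorr_range_min)

  ds <- impute(ds, pca, k = config$impute_k, t = config$impute_t)
  trends <- list()
  for (nm in c("ap", "ml")) {
    genes <- selections[[nm]]$selected
    if (length(genes) >= config$trend_cluster_k + 1L) {
      ts <- fit_trends(ds, spaces[[nm]][, 1], genes = genes,
                       n_bins = config$trend_bins, axis_tag = nm)
      trends[[nm]] <- cluster_trends(ts, k = config$trend_cluster_k,
                                     seed = config$seed)
    }
  }
  hierarchy <- NULL
  if (length(selections$multiscale$selected) >= 3L)
    hierarchy <- module_hierarchy(ds, selections$multiscale$selected,
                                  cut_distances = config$cut_distances)

  list(dataset = ds, hvg = hv, pca = pca, diffusion = dr,
       n_components_selected = n_sel, multiscale = ms,
       ap_component = ap_match, ml_component = ml_match,
       autocorr = autocorr, selections = selections,
       trends = trends, hierarchy = hierarchy, config = config)
}
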