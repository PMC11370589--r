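#' Diffusion map of a cell-cell similarity graph
#'
#' From the symmetric non-negative weight matrix W, the Markov matrix
#' M = D^-1 W is diagonalized via its symmetric conjugate
#' S = D^-1/2 W D^-1/2; eigenvectors are mapped back by D^-1/2 and the
#' stationary eigenvector (eigenvalue 1) is dropped. Components are labeled
#' DC0, DC1, ... in descending-eigenvalue order, with a deterministic sign
#' convention: the entry of largest magnitude of each eigenvector is
#' positive. On a disconnected graph the map is computed on the giant
#' component (warning); other cells get missing coordinates.
#'
#' @param g a \code{plate_graph} with adaptive-Gaussian weights
#' @param n_components number of non-stationary components, default 40
#' @return a \code{diffusion_result}: \code{embedding}
#'   (a \code{plate_embedding} of name \code{"diffusion"} whose
#'   \code{eigenvalues} exclude the stationary one) plus the raw pieces
#' @export
diffusion_map <- function(g, n_components = 40L) {
  W <- g$weights
  n <- nrow(W)
  ig <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(ig)
  in_giant <- comp$membership == which.max(comp$csize)
  if (!all(in_giant))
    warning("graph is disconnected; diffusion computed on the giant component (",
            sum(in_giant), "/", n, " cells)")
  Wg <- W[in_giant, in_giant, drop = FALSE]
  d <- Matrix::rowSums(Wg)
  if (any(d == 0)) stop("isolated node in giant component")
  dhi <- 1 / sqrt(d)
  S <- Matrix::Diagonal(x = dhi) %*% Wg %*% Matrix::Diagonal(x = dhi)
  S <- as.matrix((S + Matrix::t(S)) / 2)
  eg <- eigen(S, symmetric = TRUE)
  m <- min(n_components + 1L, ncol(eg$vectors))
  lam <- eg$values[seq_len(m)]
  phi <- eg$vectors[, seq_len(m), drop = FALSE]
  psi <- phi * dhi                       # right eigenvectors of M
  # drop the stationary component (largest eigenvalue, = 1)
  lam_out <- lam[-1]
  psi_out <- psi[, -1, drop = FALSE]
  # deterministic sign: largest-|entry| positive
  for (j in seq_len(ncol(psi_out))) {
    i0 <- which.max(abs(psi_out[, j]))
    if (psi_out[i0, j] < 0) psi_out[, j] <- -psi_out[, j]
  }
  coords <- matrix(NA_real_, n, ncol(psi_out))
  coords[in_giant, ] <- psi_out
  rownames(coords) <- rownames(W)
  colnames(coords) <- sprintf("DC%d", seq_len(ncol(coords)) - 1L)
  emb <- structure(list(name = "diffusion", coordinates = coords,
                        eigenvalues = lam_out,
                        component_labels = colnames(coords)),
                   class = "plate_embedding")
  structure(list(embedding = emb, eigenvalues = lam_out,
                 in_giant = in_giant,
                 n_selected = if (length(lam_out) >= 3L)
                   select_eigengap(lam_out) else length(lam_out)),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> %d components, eigengap selects %d\n",
              length(x$eigenvalues), x$n_selected))
  invisible(x)
}

#' Eigengap rule for the number of diffusion components
#'
#' Returns the number of components preceding the largest gap between
#' consecutive sorted eigenvalues, searched within the first
#' \code{search_window} eigenvalues. Ties take the smallest count (logged).
#'
#' @param eigenvalues numeric vector, descending, stationary removed
#' @param search_window window size, default 40
#' @return integer: components to keep
#' @export
select_eigengap <- function(eigenvalues, search_window = 40L) {
  if (length(eigenvalues) < 3L) stop("need at least 3 eigenvalues")
  upper <- min(search_window, length(eigenvalues)) - 1L
  gaps <- eigenvalues[seq_len(upper)] - eigenvalues[seq_len(upper) + 1L]
  best <- which(gaps == max(gaps))
  if (length(best) > 1L)
    message("tied eigengaps at ", paste(best, collapse = ", "),
            "; taking the smallest")
  best[1]
}

#' Multiscale embedding of diffusion components
#'
#' Rescales component i by eigenvalue_i / (1 - eigenvalue_i), yielding a
#' Euclidean-friendly space in which distances reflect multi-step diffusion
#' proximity.
#'
#' @param dr a \code{diffusion_result}
#' @param n number of components (default: the eigengap selection)
#' @return a \code{plate_embedding} of name \code{"multiscale"}
#' @export
multiscale_embed <- function(dr, n = dr$n_selected) {
  lam <- dr$eigenvalues
  if (n < 1L) stop("n must be >= 1")
  if (n > length(lam)) stop("n exceeds available components")
  if (any(lam[seq_len(n)] >= 1))
    stop("eigenvalue >= 1 present; stationary component not removed")
  scale <- lam[seq_len(n)] / (1 - lam[seq_len(n)])
  coords <- sweep(dr$embedding$coordinates[, seq_len(n), drop = FALSE],
                  2, scale, `*`)
  structure(list(name = "multiscale", coordinates = coords,
                 eigenvalues = lam[seq_len(n)],
                 component_labels = colnames(coords)),
            class = "plate_embedding")
}

#' Correlate genes with diffusion components
#'
#' Pearson correlation (two-sided t-test p-value) of every gene's
#' normalized expression with every diffusion component, BH-adjusted per
#' component, plus the top-100 gene list per component among genes with
#' p < 0.01, sorted by |r| descending. Constant genes are recorded as
#' missing and excluded from top lists.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param emb a \code{plate_embedding}
#' @param top_n size of the per-component top list, default 100
#' @param p_max p-value gate for the top list, default 0.01
#' @return list: \code{table} (gene, component, r, p, fdr) and
#'   \code{top} (named list of top-gene data.frames per component)
#' @export
correlate_genes_dc <- function(ds, emb, top_n = 100L, p_max = 0.01) {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing")
  X <- ds$layers$normalized
  C <- emb$coordinates
  ok <- stats::complete.cases(C)
  X <- X[ok, , drop = FALSE]; C <- C[ok, , drop = FALSE]
  n <- nrow(X)
  const <- apply(X, 2, function(x) stats::var(x) == 0)
  tabs <- lapply(seq_len(ncol(C)), function(j) {
    r <- suppressWarnings(as.vector(stats::cor(X, C[, j])))
    r[const] <- NA
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    data.frame(gene_id = colnames(X), component = colnames(C)[j],
               r = r, p = p, fdr = stats::p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  top <- lapply(tabs, function(t0) {
    t1 <- t0[!is.na(t0$r) & t0$p < p_max, , drop = FALSE]
    t1 <- t1[order(-abs(t1$r)), , drop = FALSE]
    head(t1, top_n)
  })
  names(top) <- colnames(C)
  list(table = tab, top = top)
}

#' Per-region temporal axis (DC0 against developmental stage)
#'
#' Subsets the dataset to one region and recomputes the whole geometry
#' (normalization, HVG, PCA, adaptive kNN, diffusion map) on the subset.
#' DC0 is validated against the stage index by Spearman correlation and
#' oriented so that increasing DC0 means later stages.
#'
#' @param ds a \code{plate_dataset} with \code{region} and
#'   \code{stage_index} cell fields
#' @param region region name to subset to
#' @param k neighbors for the diffusion graph, default 30
#' @param n_components diffusion components to compute, default 40
#' @return list: \code{dc0} (oriented per-cell axis), \code{result}
#'   (\code{diffusion_result}), \code{stage_correlation} (Spearman; NA for
#'   single-stage data), \code{cell_id}
#' @export
temporal_axis_per_region <- function(ds, region, k = 30L, n_components = 40L) {
  if (is.null(ds$cells$region)) stop("region labels missing")
  mask <- ds$cells$region == region
  if (!any(mask)) stop("no cells in region ", region)
  sub <- subset_dataset(ds, cell_mask = mask)
  sub <- normalize_log(sub)
  hv <- select_hvg(sub, n_top = min(3000L, ncol(sub$counts)))
  pca <- pca_to_variance(sub, hvg = hv)
  g <- knn_graph(pca, k = min(k, nrow(sub$counts) - 1L),
                 mode = "adaptive_gaussian")
  dr <- diffusion_map(g, n_components = n_components)
  dc0 <- dr$embedding$coordinates[, 1]
  stage <- sub$cells$stage_index
  rho <- NA_real_
  if (!is.null(stage) && length(unique(stage[!is.na(dc0)])) > 1L) {
    rho <- suppressWarnings(
      stats::cor(dc0, stage, method = "spearman", use = "complete.obs"))
    if (!is.na(rho) && rho < 0) { dc0 <- -dc0; rho <- -rho }
  }
  list(dc0 = dc0, result = dr, stage_correlation = rho,
       cell_id = sub$cells$cell_id)
}

#' Identify which diffusion component tracks a marker-defined axis
#'
#' Rather than hard-coding component indices, the component best matching
#' an axis is found by correlating each component with a marker signature
#' score (e.g. anterior markers for the AP axis).
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param emb a diffusion \code{plate_embedding}
#' @param gs a [gene_set()] of markers anchoring one end of the axis
#' @return list: \code{component} (label), \code{index}, \code{r} (signed
#'   Pearson correlation of that component with the signature score)
#' @export
match_axis_component <- function(ds, emb, gs) {
  sc <- signature_score(ds, gs)$z
  C <- emb$coordinates
  ok <- stats::complete.cases(C)
  r <- as.vector(stats::cor(C[ok, , drop = FALSE], sc[ok]))
  j <- which.max(abs(r))
  list(component = colnames(C)[j], index = j, r = r[j])
}
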