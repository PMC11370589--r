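#' Local autocorrelation of genes on a latent-space kNN graph
#'
#' Builds an adaptive-Gaussian kNN graph on the latent space, symmetrizes
#' it, row-normalizes and re-symmetrizes the weights. For each gene the
#' expression vector x (log-normalized layer) is standardized across cells
#' and the statistic H = sum_{i != j} w_ij x_i x_j is computed: a
#' graph-weighted Moran's-I-style measure of how coherent expression is
#' among neighboring cells. Under the null that expression is independent
#' across cells, E[H] = -S0/(n-1) (S0 the total weight, as for Moran's I)
#' and Var[H] = 2 sum_{i != j} w_ij^2 (iid-standardized approximation),
#' giving Z = (H - E[H]) / sqrt(Var[H]) and a one-sided normal p-value,
#' BH-adjusted across genes. Constant genes get Z = 0, p = 1.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param latent cells x dims matrix or \code{plate_embedding} (use a
#'   single diffusion component for per-axis analysis, the multiscale
#'   embedding for the joint analysis)
#' @param k neighbors, default 30
#' @param space_tag label recorded in the result (e.g. "DC0", "multiscale")
#' @return an \code{autocorr_result} data.frame: per gene H, Z, p, fdr, the
#'   natural-log expression range, and the space tag
#' @export
local_autocorrelation <- function(ds, latent, k = 30L, space_tag = "latent") {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing")
  if (inherits(latent, "plate_embedding")) latent <- latent$coordinates
  latent <- as.matrix(latent)
  X <- ds$layers$normalized
  if (nrow(latent) != nrow(X))
    stop("latent space rows (", nrow(latent),
         ") do not match cells (", nrow(X), ")")
  ok <- stats::complete.cases(latent)
  latent <- latent[ok, , drop = FALSE]
  X <- X[ok, , drop = FALSE]
  g <- knn_graph(latent, k = k, mode = "adaptive_gaussian")
  W <- autocorr_weights(g)
  autocorr_stat(X, W, space_tag = space_tag)
}

# Symmetric kNN weights -> row-normalized, re-symmetrized autocorrelation
# weights (diagonal zero).
autocorr_weights <- function(g) {
  W <- g$weights
  Matrix::diag(W) <- 0
  rs <- Matrix::rowSums(W)
  rs[rs == 0] <- 1
  A <- Matrix::Diagonal(x = 1 / rs) %*% W
  W2 <- (A + Matrix::t(A)) / 2
  Matrix::drop0(W2)
}

# Core statistic on a cells x genes matrix and a symmetric weight matrix.
autocorr_stat <- function(X, W, space_tag = "latent") {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)          # population sd
  const <- sdv == 0
  sdv[const] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)   # standardized expression
  H <- colSums((W %*% Z) * Z)                # x' W x per gene (diag(W)=0)
  # Null moments under random relabeling of standardized x (the Moran's I
  # randomization null): E[H] = -S0/(n-1) with S0 = sum_{i!=j} w_ij, and
  # Var[H] = sum_{i!=j} (w_ij^2 + w_ij w_ji) = 2 sum_{i!=j} w_ij^2 for
  # symmetric W (iid-standardized approximation).
  EH <- -sum(W@x) / (n - 1)
  varH <- 2 * sum(W@x^2)
  zscore <- (H - EH) / sqrt(varH)
  zscore[const] <- 0
  p <- stats::pnorm(zscore, lower.tail = FALSE)
  p[const] <- 1
  rng <- apply(X, 2, function(x) diff(range(x)))
  structure(data.frame(
    gene_id = colnames(X), H = as.numeric(H), Z = as.numeric(zscore),
    p = p, fdr = stats::p.adjust(p, "BH"), ln_range = rng,
    space = space_tag, stringsAsFactors = FALSE),
    class = c("autocorr_result", "data.frame"))
}

#' Select spatially informative genes from an autocorrelation result
#'
#' Filters, in order: natural-log expression range > \code{range_min}
#' (removes lowly expressed genes); FDR < \code{fdr_max}; Z >= the cutoff —
#' either the fixed \code{z_min} or a knee point over the descending sorted
#' Z curve of all range-passing genes (\code{z_mode = "knee"}). Returns the
#' result with a \code{selected} flag and the genes sorted by Z descending.
#'
#' @param ar an \code{autocorr_result}
#' @param fdr_max FDR ceiling, default 1e-5
#' @param z_min fixed Z cutoff, default 10
#' @param z_mode \code{"fixed"} or \code{"knee"}
#' @param range_min expression-range floor (ln units), default 1
#' @return list: \code{result} (the annotated table), \code{selected}
#'   (gene ids by descending Z), \code{z_cutoff} used, \code{z_mode}
#' @export
select_spatial_genes <- function(ar, fdr_max = 1e-5, z_min = 10,
                                 z_mode = c("fixed", "knee"), range_min = 1) {
  z_mode <- match.arg(z_mode)
  pass_range <- ar$ln_range > range_min
  cutoff <- z_min
  if (z_mode == "knee") {
    zs <- sort(ar$Z[pass_range], decreasing = TRUE)
    if (length(zs) >= 3L) cutoff <- zs[knee_point(zs)]
  }
  sel <- pass_range & ar$fdr < fdr_max & ar$Z >= cutoff
  ar$selected <- sel
  genes <- ar$gene_id[sel][order(ar$Z[sel], decreasing = TRUE)]
  if (length(genes) == 0L)
    message("no genes pass the spatial selection thresholds")
  list(result = ar, selected = genes, z_cutoff = cutoff, z_mode = z_mode)
}

#' Knee point of a curve
#'
#' The index maximizing the perpendicular distance to the chord joining the
#' first and last points (kneedle-style), with ties going to the smallest
#' index. A straight line has distance 0 everywhere and returns index 1
#' with a warning.
#'
#' @param curve numeric vector (>= 3 points), typically monotone
#' @return integer index into \code{curve}
#' @export
knee_point <- function(curve) {
  m <- length(curve)
  if (m < 3L) stop("knee_point needs at least 3 points")
  x <- seq_len(m) - 1
  x1 <- x[1]; y1 <- curve[1]; x2 <- x[m]; y2 <- curve[m]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * x - (x2 - x1) * curve + x2 * y1 - y2 * x1) / denom
  if (max(d) < .Machine$double.eps^0.5) {
    warning("curve is a straight line; no knee, returning index 1")
    return(1L)
  }
  which.max(d)
}

#' Diffusion imputation of expression (MAGIC-style smoothing)
#'
#' Builds a small-k adaptive-Gaussian graph, row-normalizes it into a
#' Markov matrix M, and stores M^t times the normalized layer as the
#' \code{"imputed"} layer. Used for trend fitting and display only — never
#' for test statistics, to avoid inflating autocorrelation.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param coords cells x dims coordinates (or \code{plate_embedding}) to
#'   build the graph on (typically PCA)
#' @param k graph neighbors, default 5
#' @param t diffusion steps, default 3 (t = 0 leaves the layer unchanged)
#' @return the dataset with an \code{"imputed"} layer added
#' @export
impute <- function(ds, coords, k = 5L, t = 3L) {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing")
  X <- ds$layers$normalized
  if (t == 0L) {
    ds$layers$imputed <- X
    return(ds)
  }
  g <- knn_graph(coords, k = k, mode = "adaptive_gaussian")
  W <- g$weights
  rs <- Matrix::rowSums(W)
  rs[rs == 0] <- 1
  M <- Matrix::Diagonal(x = 1 / rs) %*% W
  Y <- X
  for (i in seq_len(t)) Y <- as.matrix(M %*% Y)
  dimnames(Y) <- dimnames(X)
  ds$layers$imputed <- Y
  ds
}

#' Fit smoothed gene expression trends along an axis
#'
#' Per gene, a penalized cubic-spline generalized additive model (8 basis
#' functions at axis quantiles, smoothness by generalized cross-validation)
#' of the imputed expression on the axis, predicted at \code{n_bins}
#' equally spaced axis values between the axis minimum and maximum.
#'
#' @param ds a \code{plate_dataset} with an \code{"imputed"} (preferred) or
#'   \code{"normalized"} layer
#' @param axis numeric per-cell axis values (finite)
#' @param genes gene ids to fit (default: all)
#' @param n_bins prediction grid size, default 500
#' @param axis_tag label recorded in the result
#' @return a \code{trend_set}: \code{trends} (genes x n_bins), \code{grid},
#'   \code{axis_tag}; cluster labels are added by [cluster_trends()]
#' @export
fit_trends <- function(ds, axis, genes = NULL, n_bins = 500L,
                       axis_tag = "axis") {
  X <- if (!is.null(ds$layers$imputed)) ds$layers$imputed else ds$layers$normalized
  if (is.null(X)) stop("no expression layer; run normalize_log/impute first")
  stopifnot(length(axis) == nrow(X), all(is.finite(axis)))
  if (length(axis) < 50L) stop("need at least 50 cells for trend fitting")
  if (is.null(genes)) genes <- colnames(X)
  genes <- intersect(genes, colnames(X))
  grid <- seq(min(axis), max(axis), length.out = n_bins)
  trends <- matrix(NA_real_, length(genes), n_bins,
                   dimnames = list(genes, NULL))
  for (gi in seq_along(genes)) {
    y <- X[, genes[gi]]
    if (stats::var(y) == 0) {
      trends[gi, ] <- y[1]
      next
    }
    fit <- mgcv::gam(y ~ s(axis, bs = "cr", k = 8), method = "GCV.Cp")
    trends[gi, ] <- as.numeric(stats::predict(fit,
                                              newdata = data.frame(axis = grid)))
  }
  structure(list(trends = trends, grid = grid, axis_tag = axis_tag,
                 cluster = NULL),
            class = "trend_set")
}

#' @export
print.trend_set <- function(x, ...) {
  cat(sprintf("<trend_set:%s> %d genes x %d bins%s\n", x$axis_tag,
              nrow(x$trends), ncol(x$trends),
              if (!is.null(x$cluster))
                sprintf(", %d clusters", length(unique(x$cluster))) else ""))
  invisible(x)
}

#' Cluster gene trends
#'
#' Each trend is z-normalized across bins, an adaptive-Gaussian kNN graph
#' (Euclidean, \code{k} neighbors) is built between genes, and graph
#' community detection ([graph_cluster()]) assigns labels, re-ordered by the mean
#' axis position of each cluster's trend peaks (anterior-peaked clusters
#' first).
#'
#' @param ts a \code{trend_set}
#' @param k trend-graph neighbors, default 20
#' @param seed clustering seed
#' @return the \code{trend_set} with integer \code{cluster} labels
#'   (0-based, peak-ordered)
#' @export
cluster_trends <- function(ts, k = 20L, seed = 0L) {
  Tm <- ts$trends
  if (nrow(Tm) < k + 1L)
    stop("need at least k+1 = ", k + 1L, " genes; have ", nrow(Tm),
         " (use a smaller k)")
  Z <- t(apply(Tm, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  g <- knn_graph(Z, k = k, mode = "adaptive_gaussian")
  cl <- graph_cluster(g, seed = seed)
  peak <- apply(Tm, 1, which.max)
  mean_peak <- tapply(peak, cl, mean)
  ord <- order(mean_peak)
  relabel <- integer(length(ord))
  relabel[as.integer(names(mean_peak)[ord]) + 1L] <- seq_along(ord) - 1L
  ts$cluster <- relabel[cl + 1L]
  ts
}

#' Multiscale gene-module hierarchy
#'
#' Genes are represented by their rows of the gene-gene Pearson
#' correlation matrix (computed on the log-normalized layer); Ward linkage
#' on Euclidean distances between these rows builds the hierarchy. Labels
#' are extracted at each requested linkage-distance cutoff, and a default
#' cut is chosen by knee point on the curve of median intra-cluster
#' pairwise correlation (median over clusters of per-cluster medians)
#' versus number of clusters.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param genes selected gene ids (>= 3); constant genes are dropped with a
#'   warning
#' @param cut_distances linkage-height cutoffs, default c(10, 6, 4)
#' @param max_k largest cluster count scanned for the knee curve
#' @return a \code{module_hierarchy}: \code{hclust} tree, \code{cuts}
#'   (labels per cutoff), \code{knee_k} and \code{knee_labels} (default
#'   cut), \code{correlation_curve}, and per-cut median intra-cluster
#'   correlation
#' @export
module_hierarchy <- function(ds, genes, cut_distances = c(10, 6, 4),
                             max_k = 30L) {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing")
  X <- ds$layers$normalized[, intersect(genes, colnames(ds$layers$normalized)),
                            drop = FALSE]
  const <- apply(X, 2, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped from module clustering")
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 3L) stop("need at least 3 non-constant genes")
  C <- stats::cor(X)
  hc <- stats::hclust(stats::dist(C), method = "ward.D2")

  # median over clusters of each cluster's median intra-cluster pairwise
  # correlation (per-cluster medians keep a half-merged cut from looking as
  # coherent as the true cut)
  intra_median <- function(labels) {
    vals <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      if (length(ix) < 2L) return(NULL)
      cc <- C[ix, ix]
      stats::median(cc[upper.tri(cc)])
    }))
    if (is.null(vals)) NA_real_ else stats::median(vals)
  }

  ks <- seq_len(min(max_k, ncol(X)))
  curve <- vapply(ks, function(k) intra_median(stats::cutree(hc, k = k)), 0)
  curve[is.na(curve)] <- 1
  knee_k <- ks[knee_point(curve)]
  knee_labels <- stats::cutree(hc, k = knee_k)

  cuts <- lapply(cut_distances, function(D) stats::cutree(hc, h = D))
  names(cuts) <- paste0("D", cut_distances)
  cut_stats <- data.frame(
    cut = c(names(cuts), "knee"),
    n_clusters = c(vapply(cuts, function(l) length(unique(l)), 0L), knee_k),
    median_intra_correlation = c(vapply(cuts, intra_median, 0),
                                 intra_median(knee_labels)))
  structure(list(hclust = hc, genes = colnames(X), cuts = cuts,
                 knee_k = knee_k, knee_labels = knee_labels,
                 correlation_curve = data.frame(k = ks, median_intra = curve),
                 cut_stats = cut_stats),
            class = "module_hierarchy")
}

#' @export
print.module_hierarchy <- function(x, ...) {
  cat(sprintf("<module_hierarchy> %d genes; knee cut: %d clusters\n",
              length(x$genes), x$knee_k))
  print(x$cut_stats, row.names = FALSE)
  invisible(x)
}

#' Per-cell scores of gene modules
#'
#' Scores every module of a hierarchy cut as a positive-only signature
#' ([signature_score()]): the z-normalized mean expression of its genes.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param hierarchy a \code{module_hierarchy}
#' @param cut one of the names of \code{hierarchy$cuts}, or \code{"knee"}
#' @return cells x modules matrix of z scores
#' @export
module_cell_scores <- function(ds, hierarchy, cut = "knee") {
  labels <- if (identical(cut, "knee")) hierarchy$knee_labels
            else hierarchy$cuts[[cut]]
  if (is.null(labels)) stop("unknown cut: ", cut)
  mods <- split(hierarchy$genes, labels)
  sets <- lapply(names(mods), function(m)
    gene_set(paste0("module", m), mods[[m]]))
  names(sets) <- vapply(sets, function(s) s$name, "")
  score_signatures(ds, sets)
}
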