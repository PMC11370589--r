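#' Median library-size normalization and natural-log transform
#'
#' Scales each cell's counts by (median library size / cell library size),
#' then applies ln(x + 1), storing the result as the \code{"normalized"}
#' layer. Normalization is sample-set dependent: after subsetting, recompute
#' it (the median changes), as is done per region downstream.
#'
#' @param ds a \code{plate_dataset}
#' @return the dataset with a dense \code{"normalized"} layer added
#' @export
normalize_log <- function(ds) {
  lib <- Matrix::rowSums(ds$counts)
  if (any(lib == 0)) stop("zero-library cell present; run QC first")
  f <- stats::median(lib) / lib
  norm <- log1p(as.matrix(Matrix::Diagonal(x = f) %*% ds$counts))
  dimnames(norm) <- dimnames(ds$counts)
  ds$layers$normalized <- norm
  ds
}

#' Variance-stabilized highly variable gene selection
#'
#' Ranks genes by standardized variance on raw counts: a loess trend of
#' log10 variance on log10 mean is fit across genes, counts are
#' standardized per gene by the trend-predicted standard deviation, clipped
#' at sqrt(n cells), and the variance of the clipped values is the ranking
#' statistic (the vst flavor of HVG selection). Mitochondrial genes,
#' ribosomal genes and genes expressed in fewer than \code{min_cells} cells
#' are excluded from ranking; curated marker genes are force-retained and
#' flagged.
#'
#' @param ds a \code{plate_dataset}
#' @param n_top number of genes to select, default 3000
#' @param curated gene ids force-retained regardless of rank
#' @param min_cells expression-breadth floor, default 10
#' @return an \code{hvg_result} data.frame: per gene the standardized
#'   variance, \code{selected} flag, \code{exclusion_reason}
#'   (mito/ribo/rare/none) and \code{curated} flag
#' @export
select_hvg <- function(ds, n_top = 3000L, curated = character(0),
                       min_cells = 10L) {
  counts <- ds$counts
  n <- nrow(counts)
  mu <- Matrix::colSums(counts) / n
  ex2 <- Matrix::colSums(counts^2) / n
  v <- (ex2 - mu^2) * n / max(1, n - 1)

  reason <- rep("none", ncol(counts))
  reason[ds$genes$n_cells_expressing < min_cells] <- "rare"
  reason[ds$genes$is_ribo] <- "ribo"
  reason[ds$genes$is_mito] <- "mito"
  eligible <- reason == "none" & mu > 0 & v > 0

  std_var <- rep(NA_real_, ncol(counts))
  if (sum(eligible) >= 3L) {
    lmu <- log10(mu[eligible]); lv <- log10(v[eligible])
    fit <- stats::loess(lv ~ lmu, span = 0.3, degree = 2)
    sd_hat <- sqrt(10^stats::predict(fit, lmu))
    clip <- sqrt(n)
    idx <- which(eligible)
    # variance of clipped standardized counts, computed gene by gene on the
    # sparse structure: clipped z has value -mu/sd at zeros
    Xc <- counts[, idx, drop = FALSE]
    sv <- vapply(seq_along(idx), function(j) {
      x <- Xc[, j]
      z <- (as.numeric(x) - mu[idx[j]]) / sd_hat[j]
      z <- pmin(pmax(z, -clip), clip)
      sum((z - mean(z))^2) / (n - 1)
    }, 0)
    std_var[idx] <- sv
  }

  sel <- rep(FALSE, ncol(counts))
  rankable <- which(!is.na(std_var))
  n_eff <- min(n_top, length(rankable))
  if (n_top > length(rankable))
    warning("n_top exceeds eligible genes; selecting all ", length(rankable))
  sel[rankable[order(std_var[rankable], decreasing = TRUE)[seq_len(n_eff)]]] <- TRUE
  cur <- colnames(counts) %in% curated
  sel[cur] <- TRUE

  structure(data.frame(gene_id = colnames(counts),
                       standardized_variance = std_var,
                       selected = sel, exclusion_reason = reason,
                       curated = cur, stringsAsFactors = FALSE),
            class = c("hvg_result", "data.frame"))
}

#' Remove cell-cycle influence by score regression
#'
#' Computes a per-cell signature score for each cell-cycle gene set
#' ([signature_score()]; the raw signed score is used — the per-cell
#' z-scaling helps cross-signature comparison but distorts a nuisance
#' covariate), then residualizes every gene's normalized expression on the
#' score vectors by ordinary least squares, re-centering residuals to
#' preserve each gene's original mean. A linear stand-in for factor-model
#' detrending: it removes the component of expression linearly explained
#' by cell-cycle scores.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param cc_sets list of [gene_set()] objects for cell-cycle phases
#' @return the dataset with its \code{"normalized"} layer residualized
#' @export
regress_cell_cycle <- function(ds, cc_sets) {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing")
  scores <- lapply(cc_sets, function(gs) {
    tryCatch(signature_score(ds, gs)$raw, error = function(e) NULL)
  })
  scores <- scores[!vapply(scores, is.null, TRUE)]
  if (length(scores) == 0L) {
    warning("no cell-cycle genes present; normalized layer unchanged")
    return(ds)
  }
  S <- cbind(1, do.call(cbind, scores))
  X <- ds$layers$normalized
  beta <- solve(crossprod(S), crossprod(S, X))
  resid <- X - S %*% beta
  resid <- sweep(resid, 2, colMeans(X), `+`)   # re-center to original means
  dimnames(resid) <- dimnames(X)
  ds$layers$normalized <- resid
  ds
}

#' PCA retaining a target fraction of variance
#'
#' Exact singular value decomposition of the gene-centered log-normalized
#' HVG matrix (genes centered, not scaled to unit variance). The number of
#' components kept is the smallest m whose cumulative explained-variance
#' ratio reaches \code{target}, capped at min(cells, genes) - 1.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param hvg optional \code{hvg_result}; if given, PCA is restricted to the
#'   selected genes
#' @param target cumulative explained-variance target, default 0.75
#' @return a \code{plate_embedding} of name \code{"pca"} with
#'   \code{coordinates} (cells x m), \code{explained_variance_ratio} for all
#'   computed components, and \code{n_selected = m}
#' @export
pca_to_variance <- function(ds, hvg = NULL, target = 0.75) {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing")
  X <- ds$layers$normalized
  if (!is.null(hvg)) X <- X[, hvg$selected, drop = FALSE]
  if (nrow(X) < 2L) stop("PCA needs at least 2 cells")
  X <- sweep(X, 2, colMeans(X))
  keep <- apply(X, 2, function(col) any(col != 0))
  X <- X[, keep, drop = FALSE]
  max_m <- min(nrow(X), ncol(X)) - 1L
  sv <- svd(X, nu = max_m, nv = 0)
  evr <- (sv$d^2)[seq_len(max_m)] / sum(sv$d^2)
  cum <- cumsum(evr)
  m <- if (target >= cum[max_m]) max_m else which(cum >= target)[1]
  coords <- sv$u[, seq_len(m), drop = FALSE] %*% diag(sv$d[seq_len(m)], m)
  rownames(coords) <- rownames(ds$counts)
  colnames(coords) <- sprintf("PC%d", seq_len(m))
  structure(list(name = "pca", coordinates = coords,
                 eigenvalues = numeric(0),
                 explained_variance_ratio = evr,
                 n_selected = m,
                 component_labels = colnames(coords)),
            class = "plate_embedding")
}

#' @export
print.plate_embedding <- function(x, ...) {
  cat(sprintf("<plate_embedding:%s> %d cells x %d components\n",
              x$name, nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' Exact k-nearest-neighbor graph
#'
#' Euclidean kNN with deterministic tie-breaking by lower cell index.
#' Weights are either unit (for community detection) or adaptive Gaussian
#' exp(-d^2 / sigma_i^2) with sigma_i the distance from cell i to its
#' ceiling(k/3)-th neighbor (for diffusion maps and autocorrelation).
#' The graph is symmetrized by taking max(w_ij, w_ji); the diagonal is zero.
#'
#' @param coords cells x dims coordinate matrix, or a
#'   \code{plate_embedding}
#' @param k neighbors per cell, default 30
#' @param mode \code{"unit"} or \code{"adaptive_gaussian"}
#' @return a \code{plate_graph}: sparse symmetric \code{weights}, \code{k},
#'   \code{mode}
#' @export
knn_graph <- function(coords, k = 30L, mode = c("adaptive_gaussian", "unit")) {
  mode <- match.arg(mode)
  if (inherits(coords, "plate_embedding")) coords <- coords$coordinates
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nn_idx <- matrix(0L, n, k)
  nn_d <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))[seq_len(k)]  # ties by lower index
    nn_idx[i, ] <- ord
    nn_d[i, ] <- D[i, ord]
  }
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn_idx))
  dd <- as.vector(t(nn_d))
  if (mode == "unit") {
    w <- rep(1, length(dd))
  } else {
    sig_k <- ceiling(k / 3)
    sigma <- nn_d[, sig_k]
    sigma[sigma == 0] <- min(nn_d[nn_d > 0], 1e-12)
    w <- exp(-(dd^2) / (sigma[ii]^2))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W <- pmax_sparse(A, Matrix::t(A))
  dimnames(W) <- list(rownames(coords), rownames(coords))
  structure(list(weights = W, k = as.integer(k), mode = mode,
                 symmetric = TRUE),
            class = "plate_graph")
}

# elementwise max of two sparse matrices
pmax_sparse <- function(A, B) {
  S <- A + B
  M <- (A - B)
  # max(a,b) = (a + b + |a - b|) / 2
  M@x <- abs(M@x)
  out <- (S + M) / 2
  Matrix::drop0(out)
}

#' @export
print.plate_graph <- function(x, ...) {
  cat(sprintf("<plate_graph> %d cells, k=%d, mode=%s, %d edges\n",
              nrow(x$weights), x$k, x$mode,
              length(x$weights@x)))
  invisible(x)
}
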