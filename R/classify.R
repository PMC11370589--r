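#' Graph community detection (Leiden modularity clustering)
#'
#' Modularity-maximizing Leiden clustering on a unit-weight kNN graph.
#' Labels are integers 0..C-1 ordered by descending cluster size; isolated
#' nodes become singleton clusters. Deterministic under a fixed seed.
#'
#' @param g a \code{plate_graph} (unit mode recommended)
#' @param seed integer seed
#' @param resolution Leiden resolution parameter
#' @return integer vector of cluster labels (0-based)
#' @export
graph_cluster <- function(g, seed = 0L, resolution = 1) {
  W <- g$weights
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(ig, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes)[ord])] <- seq_along(ord) - 1L
  as.integer(relabel[memb])
}

#' Signed per-cell signature score
#'
#' Raw score: mean normalized expression over the positive genes minus mean
#' over the negative genes (0 if no negatives). The score is z-normalized
#' against the analytic null of a random signature of the same size drawn
#' from the cell's gene-expression distribution: with mean mu_c and
#' variance v_c of all genes' normalized expression in cell c,
#' z = (s - 0) / sqrt(v_c (1/m+ + 1/m-)) when negatives are present and
#' z = (s - mu_c) / sqrt(v_c / m+) otherwise. Genes absent from the dataset
#' are dropped with a warning.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param gs a [gene_set()]
#' @return data.frame with per-cell \code{raw} and \code{z} scores and the
#'   set sizes actually used (\code{m_pos}, \code{m_neg})
#' @export
signature_score <- function(ds, gs) {
  if (is.null(ds$layers$normalized)) stop("normalized layer missing")
  X <- ds$layers$normalized
  pos <- intersect(gs$positive_genes, colnames(X))
  neg <- intersect(gs$negative_genes, colnames(X))
  n_missing <- length(gs$positive_genes) - length(pos) +
    length(gs$negative_genes) - length(neg)
  if (n_missing > 0)
    warning("gene set '", gs$name, "': ", n_missing,
            " gene(s) absent from dataset, dropped")
  if (length(pos) == 0L)
    stop("gene set '", gs$name, "' has no positive genes in the dataset")
  mu_c <- rowMeans(X)
  v_c <- apply(X, 1, stats::var)
  v_c[v_c == 0] <- .Machine$double.eps
  s_pos <- rowMeans(X[, pos, drop = FALSE])
  if (length(neg) > 0L) {
    s <- s_pos - rowMeans(X[, neg, drop = FALSE])
    z <- s / sqrt(v_c * (1 / length(pos) + 1 / length(neg)))
  } else {
    s <- s_pos
    z <- (s - mu_c) / sqrt(v_c / length(pos))
  }
  data.frame(cell_id = rownames(X), raw = s, z = z,
             m_pos = length(pos), m_neg = length(neg),
             stringsAsFactors = FALSE)
}

#' Score a dataset against several signatures
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param gene_sets named list of [gene_set()] objects
#' @return cells x signatures matrix of z scores; signatures with no usable
#'   positive genes yield an all-NA column with a warning
#' @export
score_signatures <- function(ds, gene_sets) {
  cols <- lapply(gene_sets, function(gs) {
    tryCatch(signature_score(ds, gs)$z, error = function(e) {
      warning("signature '", gs$name, "' unusable: ", conditionMessage(e))
      rep(NA_real_, nrow(ds$counts))
    })
  })
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(ds$counts)
  colnames(out) <- vapply(gene_sets, function(g) g$name, "")
  out
}

#' Build a high-confidence training set from signature scores
#'
#' Per type t, the threshold is the 20th percentile of the t-score among
#' cells preliminarily labeled t. A cell trains for its own type iff its
#' own-type score exceeds its type's threshold and every other type's score
#' falls below that type's threshold; all other cells become unlabeled.
#'
#' @param scores cells x types z-score matrix (from [score_signatures()])
#' @param prelim character vector of preliminary labels per cell (must be
#'   column names of \code{scores})
#' @param probs quantile defining the threshold, default 0.20
#' @return character vector: the training label per cell, or NA for
#'   unlabeled cells
#' @export
build_training_labels <- function(scores, prelim, probs = 0.20) {
  types <- colnames(scores)
  stopifnot(all(stats::na.omit(prelim) %in% types))
  thr <- vapply(types, function(t) {
    own <- scores[which(prelim == t), t]
    if (length(own) == 0L) return(NA_real_)
    stats::quantile(own, probs = probs, names = FALSE, na.rm = TRUE)
  }, 0)
  thr_cmp <- ifelse(is.na(thr), Inf, thr)   # types with no prelim cells claim nothing
  lab <- rep(NA_character_, nrow(scores))
  for (i in seq_len(nrow(scores))) {
    t0 <- prelim[i]
    if (is.na(t0) || is.na(thr[t0])) next
    above <- !is.na(scores[i, ]) & scores[i, ] > thr_cmp
    if (above[t0] && sum(above) == 1L) lab[i] <- t0
  }
  empty <- types[!types %in% lab]
  if (length(empty))
    stop("no training cells survive for type(s): ",
         paste(empty, collapse = ", "))
  lab
}

#' Semi-supervised classification by absorbing Markov chain
#'
#' The graph's weights are row-normalized into a transition matrix;
#' training cells are made absorbing. For the unlabeled set U the linear
#' system (I - Q) B0 = R is solved, with Q the U-to-U block and R the
#' U-to-labeled block, and B0 aggregated by label into absorption
#' probabilities. Each cell is assigned the label with maximum absorption
#' probability; ties break by label order with a warning. Unlabeled cells
#' with no path to any absorbing cell get a uniform row and a warning.
#'
#' @param g a \code{plate_graph} over all cells
#' @param labels character vector: training label per cell, NA = unlabeled
#' @return list: \code{absorption} (cells x labels; training cells one-hot),
#'   \code{assigned} label per cell, \code{is_training} flag
#' @export
absorption_classify <- function(g, labels) {
  W <- g$weights
  n <- nrow(W)
  stopifnot(length(labels) == n)
  lab_levels <- sort(unique(stats::na.omit(labels)))
  if (length(lab_levels) < 1L) stop("need at least one training label")
  is_lab <- !is.na(labels)
  U <- which(!is_lab); L <- which(is_lab)

  B <- matrix(0, n, length(lab_levels),
              dimnames = list(rownames(W), lab_levels))
  B[cbind(L, match(labels[L], lab_levels))] <- 1

  if (length(U) > 0L) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    P <- Matrix::Diagonal(x = 1 / rs) %*% W
    Q <- P[U, U, drop = FALSE]
    R <- P[U, L, drop = FALSE]
    A <- Matrix::Diagonal(length(U)) - Q
    # aggregate R by label before solving: (I-Q) B0 = R %*% indicator
    ind <- Matrix::sparseMatrix(i = seq_along(L),
                                j = match(labels[L], lab_levels),
                                x = 1,
                                dims = c(length(L), length(lab_levels)))
    B0 <- as.matrix(Matrix::solve(A, R %*% ind))
    bad <- rowSums(B0) < 1e-8
    if (any(bad)) {
      warning(sum(bad), " unlabeled cell(s) unreachable from any training cell; uniform row assigned")
      B0[bad, ] <- 1 / length(lab_levels)
    }
    B0 <- B0 / rowSums(B0)
    B[U, ] <- B0
  }
  amax <- apply(B, 1, function(r) {
    w <- which(r == max(r))
    w[1]
  })
  n_ties <- sum(apply(B, 1, function(r) sum(r == max(r)) > 1L))
  if (n_ties > 0)
    warning(n_ties, " cell(s) had tied absorption probabilities; broken by label order")
  list(absorption = B, assigned = lab_levels[amax], is_training = is_lab)
}

#' Assign spatial regions to neural plate cells
#'
#' The full typing loop on a dataset: Leiden clustering of a unit kNN graph
#' on PCA coordinates, preliminary region per cluster by maximum mean
#' signature score (ties broken by set order, logged), training-set
#' construction at the 20th-percentile thresholds, and absorbing-Markov
#' classification on a k=30 adaptive graph. Fills the \code{region} cell
#' field.
#'
#' @param ds a \code{plate_dataset} with a \code{"normalized"} layer
#' @param region_sets named list of [gene_set()] objects, one per region
#' @param k_cluster neighbors for the clustering graph, default 30
#' @param k_classify neighbors for the classification graph, default 30
#' @param resolution Leiden resolution for the preliminary clustering;
#'   the default 4 clusters finely so that small domains (the midline) get
#'   their own clusters
#' @param seed seed for clustering
#' @return the dataset with \code{region} (and \code{cluster_id}) filled
#' @export
assign_regions <- function(ds, region_sets, k_cluster = 30L,
                           k_classify = 30L, resolution = 4, seed = 0L) {
  if (is.null(ds$layers$normalized)) ds <- normalize_log(ds)
  hv <- suppressWarnings(select_hvg(ds, n_top = min(3000L, ncol(ds$counts))))
  pca <- pca_to_variance(ds, hvg = hv)
  gcl <- knn_graph(pca, k = min(k_cluster, nrow(ds$counts) - 1L), mode = "unit")
  cl <- graph_cluster(gcl, seed = seed, resolution = resolution)
  ds$cells$cluster_id <- cl

  scores <- score_signatures(ds, region_sets)
  prelim <- rep(NA_character_, nrow(scores))
  for (cc in sort(unique(cl))) {
    m <- colMeans(scores[cl == cc, , drop = FALSE], na.rm = TRUE)
    best <- which(m == max(m, na.rm = TRUE))
    if (length(best) > 1L)
      message("cluster ", cc, ": tied signatures, taking first by set order")
    prelim[cl == cc] <- colnames(scores)[best[1]]
  }
  train <- build_training_labels(scores, prelim)
  gcls <- knn_graph(pca, k = min(k_classify, nrow(ds$counts) - 1L),
                    mode = "adaptive_gaussian")
  res <- absorption_classify(gcls, train)
  ds$cells$region <- res$assigned
  attr(ds, "region_classifier") <- res
  ds
}
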