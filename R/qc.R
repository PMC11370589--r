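#' Basic per-cell quality filters
#'
#' Removes cells failing any of three filters: (1) library size
#' \code{total_umis > min_umis}; (2) percent mitochondrial UMIs
#' \code{pct_mito < max_mito}; (3) library complexity — ordinary least
#' squares of log10(genes detected) on log10(total UMIs) across cells, a
#' cell fails when its residual falls below \code{-complexity_resid}
#' (too few distinct genes for its library size, the signature of cells
#' dominated by one gene program). Each removed cell gets exactly one
#' primary reason, checked in filter order (libsize, mito, complexity).
#'
#' @param ds a \code{plate_dataset} with populated cell statistics
#' @param min_umis minimum library size (exclusive), default 1000
#' @param max_mito maximum mitochondrial fraction (exclusive), default 0.20
#' @param complexity_resid one-sided residual cutoff, default 0.1
#' @return list with \code{dataset} (kept cells) and \code{report}
#'   (a \code{qc_report}: counts per reason and the per-cell table)
#' @export
basic_filters <- function(ds, min_umis = 1000, max_mito = 0.20,
                          complexity_resid = 0.1) {
  cm <- ds$cells
  n <- nrow(cm)
  if (n < 10L) stop("need at least 10 cells for the complexity regression")
  lx <- log10(pmax(cm$total_umis, 1))
  ly <- log10(pmax(cm$n_genes_detected, 1))

  fail_lib <- cm$total_umis <= min_umis
  fail_mito <- cm$pct_mito >= max_mito
  # complexity: one OLS fit of log10 genes on log10 UMIs across the input
  # cells; a refit after filtering moves the line slightly, so the filter
  # is only approximately idempotent — by design it removes the worst
  # offenders and leaves mode-level removal to cluster_quality_filter
  fit <- stats::lm.fit(cbind(1, lx), ly)
  resid <- as.vector(ly - cbind(1, lx) %*% fit$coefficients)
  fail_cplx <- resid < -complexity_resid
  reason <- rep("kept", n)
  reason[fail_cplx] <- "complexity"
  reason[fail_mito] <- "mito"
  reason[fail_lib] <- "libsize"
  keep <- reason == "kept"
  if (!any(keep)) stop("all cells removed by basic filters")

  report <- structure(list(
    n_input = n,
    n_removed_libsize = sum(reason == "libsize"),
    n_removed_mito = sum(reason == "mito"),
    n_removed_complexity = sum(reason == "complexity"),
    n_removed_cluster_reassignment = 0L,
    n_kept = sum(keep),
    cell_table = data.frame(cell_id = cm$cell_id, removal_reason = reason,
                            complexity_residual = as.vector(resid),
                            stringsAsFactors = FALSE)),
    class = "qc_report")
  out <- subset_dataset(ds, cell_mask = keep)
  out$cells$quality_class <- "high"
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d cells in; removed: libsize %d, mito %d, complexity %d, cluster %d; kept %d\n",
    x$n_input, x$n_removed_libsize, x$n_removed_mito,
    x$n_removed_complexity, x$n_removed_cluster_reassignment, x$n_kept))
  invisible(x)
}

#' Detect library-size modes by kernel density estimation
#'
#' Gaussian KDE (Scott's rule bandwidth, 512-point grid) on log10 library
#' size. Modes are local maxima of the density; cells are assigned to the
#' basin of the nearest mode, with basin boundaries at the density minima
#' between adjacent maxima. With exactly two modes, the higher-library-size
#' mode is labeled high quality; with more, the top two modes by density
#' height are used (with a warning); with one, the distribution is flagged
#' unimodal.
#'
#' @param ds a \code{plate_dataset} (>= 100 cells)
#' @return list with \code{n_modes}, \code{unimodal} flag,
#'   \code{mode_locations} (log10 UMIs), \code{boundaries},
#'   \code{assignment} ("high"/"low" per cell, all "high" when unimodal),
#'   and the per-mode mean/sd/n of log10 library size
#' @export
detect_library_modes <- function(ds) {
  x <- log10(pmax(ds$cells$total_umis, 1))
  if (length(x) < 100L) stop("need >= 100 cells for mode detection")
  d <- stats::density(x, bw = stats::bw.nrd(x), n = 512L)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) is_max <- c(1L, is_max)
  if (y[512] > y[511]) is_max <- c(is_max, 512L)
  modes <- d$x[is_max]
  heights <- y[is_max]

  if (length(modes) <= 1L) {
    return(list(n_modes = length(modes), unimodal = TRUE,
                mode_locations = modes, boundaries = numeric(0),
                assignment = rep("high", length(x)),
                stats = data.frame(mode = "high", mean = mean(x),
                                   sd = stats::sd(x), n = length(x))))
  }
  if (length(modes) > 2L) {
    warning(length(modes), " density modes found; using the top 2 by height")
    keep2 <- sort(order(heights, decreasing = TRUE)[1:2])
    modes <- modes[keep2]
    is_max <- is_max[keep2]
  }
  # boundary: density minimum between the two retained maxima
  seg <- seq(is_max[1], is_max[2])
  boundary <- d$x[seg[which.min(y[seg])]]
  lowmode_is_first <- modes[1] < modes[2]
  assignment <- ifelse(x <= boundary,
                       if (lowmode_is_first) "low" else "high",
                       if (lowmode_is_first) "high" else "low")
  stats_tab <- do.call(rbind, lapply(c("high", "low"), function(m) {
    xm <- x[assignment == m]
    data.frame(mode = m, mean = mean(xm), sd = stats::sd(xm), n = length(xm))
  }))
  list(n_modes = 2L, unimodal = FALSE, mode_locations = sort(modes),
       boundaries = boundary, assignment = assignment, stats = stats_tab)
}

#' Cluster-level reassignment of the low-quality library-size mode
#'
#' Cells are finely clustered by graph community detection on a k-nearest
#' neighbor graph in PCA space; each cluster's mean log10 library size is
#' compared to the high-quality mode by a two-sample Z-test, and clusters
#' significantly below it (one-sided, p < \code{p_cutoff}) are removed
#' wholesale. Per-cell mode labels are replaced by cluster-level labels:
#' filtering by phenotypic similarity rather than a single hard cutoff.
#' Gene-count statistics per cluster are reported as a secondary diagnostic.
#'
#' @param ds a \code{plate_dataset}
#' @param modes result of [detect_library_modes()] (must have 2 modes)
#' @param k neighbors for the fine clustering graph, default 8
#' @param p_cutoff one-sided Z-test p-value cutoff, default 1e-10
#' @param seed seed for the community detection
#' @return list with \code{dataset} (kept cells, \code{quality_class} set)
#'   and \code{report} (a \code{qc_report} with per-cluster statistics)
#' @export
cluster_quality_filter <- function(ds, modes, k = 8L, p_cutoff = 1e-10,
                                   seed = 0L) {
  if (is.null(modes$assignment)) stop("mode assignment missing")
  if (modes$unimodal) stop("cluster_quality_filter requires 2 library-size modes")
  x <- log10(pmax(ds$cells$total_umis, 1))
  hi <- modes$stats[modes$stats$mode == "high", ]

  prep <- ds
  prep <- normalize_log(prep)
  hv <- select_hvg(prep, n_top = min(2000L, ncol(prep$counts)))
  pca <- pca_to_variance(prep, hvg = hv, target = 0.75)
  g <- knn_graph(pca$coordinates, k = k, mode = "unit")
  cl <- graph_cluster(g, seed = seed, resolution = 4)  # fine clustering

  clusters <- sort(unique(cl))
  ctab <- do.call(rbind, lapply(clusters, function(cc) {
    xi <- x[cl == cc]
    m <- mean(xi); s <- stats::sd(xi); nn <- length(xi)
    se <- sqrt(hi$sd^2 / hi$n + ifelse(nn > 1, s^2 / nn, hi$sd^2))
    z <- (m - hi$mean) / se
    data.frame(cluster = cc, n = nn, mean_log10_umis = m,
               mean_log10_genes = mean(log10(pmax(ds$cells$n_genes_detected[cl == cc], 1))),
               z = z, p = stats::pnorm(z), stringsAsFactors = FALSE)
  }))
  ctab$removed <- ctab$p < p_cutoff
  bad <- ctab$cluster[ctab$removed]
  keep <- !(cl %in% bad)
  if (!any(keep)) stop("cluster filter removed every cell")

  out <- subset_dataset(ds, cell_mask = keep)
  out$cells$quality_class <- "high"
  report <- structure(list(
    n_input = nrow(ds$counts),
    n_removed_libsize = 0L, n_removed_mito = 0L, n_removed_complexity = 0L,
    n_removed_cluster_reassignment = sum(!keep),
    n_kept = sum(keep),
    cluster_table = ctab,
    cell_table = data.frame(
      cell_id = ds$cells$cell_id, cluster = cl,
      removal_reason = ifelse(keep, "kept", "cluster_reassignment"),
      stringsAsFactors = FALSE)),
    class = "qc_report")
  list(dataset = out, report = report)
}
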