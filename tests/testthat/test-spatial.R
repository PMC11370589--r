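test_that("constant genes get Z = 0 and p = 1; mismatched rows error", {
  ds <- simulate_null_matrix(100, 20, seed = 1L)
  ds <- normalize_log(ds)
  ds$layers$normalized[, 5] <- 2
  lat <- matrix(rnorm(100), ncol = 1)
  ar <- local_autocorrelation(ds, lat, k = 10L)
  expect_equal(ar$Z[5], 0)
  expect_equal(ar$p[5], 1)
  expect_error(local_autocorrelation(ds, matrix(rnorm(50), ncol = 1)),
               "do not match")
})

test_that("smooth latent-dependent genes reach Z >= 10 on 300 cells", {
  sim <- simulate_tissue(sim_config(seed = 5L, n_cells = 300L, n_genes = 100L,
                                    n_ap = 10L, n_ml = 0L, n_both = 0L,
                                    n_time = 0L))
  ds <- normalize_log(sim$dataset)
  ar <- local_autocorrelation(ds, matrix(sim$model$cells$ap, ncol = 1), k = 30L)
  patterned <- sim$model$genes$axis == "AP"
  expect_gte(min(ar$Z[patterned]), 10)
})

test_that("analytic Z agrees with a permutation oracle within 10%", {
  sim <- simulate_tissue(sim_config(seed = 5L, n_cells = 300L, n_genes = 60L,
                                    n_ap = 6L, n_ml = 4L, n_both = 0L,
                                    n_time = 0L, amplitude = 0.6))
  ds <- normalize_log(sim$dataset)
  lat <- matrix(sim$model$cells$ap, ncol = 1)
  ar <- local_autocorrelation(ds, lat, k = 30L)
  g <- knn_graph(lat, k = 30L, mode = "adaptive_gaussian")
  W <- plateaxes:::autocorr_weights(g)
  X <- ds$layers$normalized
  set.seed(11)
  # moderate-signal genes with |Z| <= 6 plus one strong gene
  check <- c(which(ar$Z > 1 & ar$Z <= 6)[1:3], which.max(ar$Z))
  for (j in check) {
    x <- X[, j]; x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    Hobs <- as.numeric(t(x) %*% W %*% x)
    Hp <- replicate(2000, {
      xp <- x[sample(length(x))]
      as.numeric(t(xp) %*% W %*% xp)
    })
    zperm <- (Hobs - mean(Hp)) / sd(Hp)
    expect_lt(abs(ar$Z[j] - zperm) / abs(zperm), 0.10)
  }
})

test_that("null-matrix Z scores are standard normal", {
  ds <- simulate_null_matrix(500, 600, seed = 7L)
  ds <- normalize_log(ds)
  set.seed(7)
  lat <- matrix(rnorm(500 * 3), 500, 3)
  ar <- local_autocorrelation(ds, lat, k = 30L)
  expect_lt(abs(mean(ar$Z)), 0.1)
  expect_true(sd(ar$Z) > 0.85 && sd(ar$Z) < 1.15)
  expect_gt(ks.test(ar$Z, "pnorm")$p.value, 0.01)
})

test_that("spatial selection filters and monotonicity behave as specified", {
  sim <- simulate_tissue(sim_config(seed = 1L, n_cells = 500L, n_genes = 200L,
                                    n_ap = 20L, n_ml = 10L, n_both = 5L,
                                    n_time = 0L))
  ds <- normalize_log(sim$dataset)
  ar <- local_autocorrelation(ds, matrix(sim$model$cells$ap, ncol = 1), k = 30L)
  sel <- select_spatial_genes(ar)
  # a high-Z gene with small expression range is excluded
  ar2 <- ar
  ar2$ln_range[match(sel$selected[1], ar2$gene_id)] <- 0.5
  sel2 <- select_spatial_genes(ar2)
  expect_false(sel$selected[1] %in% sel2$selected)
  # relaxing any threshold never removes a selected gene
  sel_relax <- select_spatial_genes(ar, fdr_max = 1e-3, z_min = 5,
                                    range_min = 0.5)
  expect_true(all(sel$selected %in% sel_relax$selected))
  # selected genes sorted by Z descending
  zs <- ar$Z[match(sel$selected, ar$gene_id)]
  expect_true(all(diff(zs) <= 0))
})

test_that("knee point matches an exhaustive perpendicular-distance scan", {
  scan_oracle <- function(y) {
    m <- length(y); x <- seq_len(m) - 1
    d <- vapply(seq_len(m), function(i) {
      v <- c(x[m] - x[1], y[m] - y[1])
      w <- c(x[i] - x[1], y[i] - y[1])
      abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
    }, 0)
    which(d == max(d))[1]
  }
  corner <- c(10, 10, 10, 1, 1, 1)
  expect_equal(knee_point(corner), scan_oracle(corner))
  expect_equal(knee_point(corner), 3L)   # first maximal (0-based index 2)
  spike <- c(10, 9, 8, 20, 6, 5, 4)
  expect_equal(knee_point(spike), scan_oracle(spike))
  expect_equal(knee_point(spike), 4L)
  expect_warning(k <- knee_point(c(5, 4, 3, 2, 1)), "straight line")
  expect_equal(k, 1L)
  expect_error(knee_point(c(1, 2)), "at least 3")
})

test_that("diffusion imputation: identity at t=0, fixed points, variance contraction", {
  sim <- simulate_tissue(sim_config(seed = 3L, n_cells = 200L, n_genes = 100L,
                                    n_ap = 10L, n_ml = 5L, n_both = 0L,
                                    n_time = 5L))
  ds <- normalize_log(sim$dataset)
  pca <- pca_to_variance(ds)
  ds0 <- impute(ds, pca, k = 5L, t = 0L)
  expect_identical(ds0$layers$imputed, ds$layers$normalized)
  ds$layers$normalized[, 7] <- 1.5   # constant gene is a fixed point
  ds3 <- impute(ds, pca, k = 5L, t = 3L)
  expect_equal(ds3$layers$imputed[, 7], rep(1.5, 200), tolerance = 1e-12,
               ignore_attr = TRUE)
  v_before <- apply(ds$layers$normalized, 2, var)
  v_after <- apply(ds3$layers$imputed, 2, var)
  expect_true(all(v_after <= v_before + 1e-12))
})

test_that("trend fitting recovers planted shapes along the axis", {
  set.seed(4)
  n <- 400
  axis <- sort(runif(n))
  counts <- matrix(1L, n, 3, dimnames = list(sprintf("c%03d", 1:n),
                                             c("lin", "const", "front")))
  ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE))
  ds$layers$normalized <- cbind(lin = 2 * axis + 1,
                                const = rep(3, n),
                                front = plogis((axis - 0.5) / 0.05))
  dimnames(ds$layers$normalized) <- dimnames(ds$counts)
  ts <- fit_trends(ds, axis, n_bins = 500L)
  expect_equal(ncol(ts$trends), 500L)
  # noiseless linear gene: RMSE below 1e-3 against the closed-form line
  truth <- 2 * ts$grid + 1
  expect_lt(sqrt(mean((ts$trends["lin", ] - truth)^2)), 1e-3)
  # constant gene gives a constant trend
  expect_equal(unname(ts$trends["const", ]), rep(3, 500), tolerance = 1e-8)
  # logistic front: fitted inflection within +/- 0.05 of 0.5
  fr <- ts$trends["front", ]
  infl <- ts$grid[which.min(abs(fr - (max(fr) + min(fr)) / 2))]
  expect_lt(abs(infl - 0.5), 0.05)
  expect_error(fit_trends(ds, axis[1:10]), "length")
})

test_that("trend fitting commutes with axis reversal", {
  set.seed(5)
  n <- 200
  axis <- runif(n)
  counts <- matrix(1L, n, 2, dimnames = list(sprintf("c%03d", 1:n), c("a", "b")))
  ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE))
  ds$layers$normalized <- cbind(a = sin(3 * axis) + rnorm(n, 0, 0.05),
                                b = axis^2)
  dimnames(ds$layers$normalized) <- dimnames(ds$counts)
  t_fwd <- fit_trends(ds, axis, n_bins = 100L)
  t_rev <- fit_trends(ds, -axis, n_bins = 100L)
  expect_equal(t_fwd$trends, t_rev$trends[, 100:1], tolerance = 1e-6)
})

test_that("trend clustering recovers planted templates and orders by peak", {
  set.seed(6)
  n <- 250
  axis <- sort(runif(n))
  templates <- list(function(x) plogis(-(x - 0.2) / 0.05),
                    function(x) exp(-((x - 0.35) / 0.1)^2),
                    function(x) exp(-((x - 0.6) / 0.1)^2),
                    function(x) plogis((x - 0.8) / 0.05),
                    function(x) x)
  genes_per <- 12L
  X <- do.call(cbind, lapply(templates, function(f)
    sapply(seq_len(genes_per), function(i) f(axis) + rnorm(n, 0, 0.1))))
  colnames(X) <- sprintf("g%02d", seq_len(ncol(X)))
  rownames(X) <- sprintf("c%03d", seq_len(n))
  counts <- matrix(1L, n, ncol(X), dimnames = dimnames(X))
  ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE))
  ds$layers$normalized <- X
  ts <- fit_trends(ds, axis, n_bins = 200L)
  ts <- cluster_trends(ts, k = 20L)
  truth <- rep(seq_along(templates), each = genes_per)
  # adjusted Rand index against the template assignment
  tab <- table(ts$cluster, truth)
  a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2)); d <- choose(sum(tab), 2)
  ari <- (a - b * c2 / d) / ((b + c2) / 2 - b * c2 / d)
  expect_gte(ari, 0.8)
  # anterior-peaked clusters get lower labels than posterior-peaked
  peaks <- apply(ts$trends, 1, which.max)
  mean_peak <- tapply(peaks, ts$cluster, mean)
  expect_true(all(diff(mean_peak[order(as.integer(names(mean_peak)))]) > 0))
  expect_error(cluster_trends(ts, k = 100L), "smaller k")
})

test_that("identical trends collapse to one cluster", {
  ts <- structure(list(trends = matrix(rep(sin(1:50), each = 25), 25, 50,
                                       dimnames = list(sprintf("g%02d", 1:25),
                                                       NULL)),
                       grid = seq_len(50), axis_tag = "x", cluster = NULL),
                  class = "trend_set")
  ts <- cluster_trends(ts, k = 10L)
  expect_equal(length(unique(ts$cluster)), 1L)
})

test_that("module hierarchy recovers planted modules with pure knee cut", {
  set.seed(7)
  n <- 300; per <- 20L
  factors <- matrix(rnorm(n * 3), n, 3)
  X <- do.call(cbind, lapply(1:3, function(k)
    sapply(seq_len(per), function(i) factors[, k] + rnorm(n, 0, 0.5))))
  colnames(X) <- sprintf("g%02d", seq_len(ncol(X)))
  rownames(X) <- sprintf("c%03d", seq_len(n))
  counts <- matrix(1L, n, ncol(X), dimnames = dimnames(X))
  ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE))
  ds$layers$normalized <- X
  mh <- module_hierarchy(ds, colnames(X), cut_distances = c(10, 6, 4))
  expect_equal(mh$knee_k, 3L)
  truth <- rep(1:3, each = per)
  tab <- table(mh$knee_labels, truth)
  expect_equal(sum(apply(tab, 1, max)), ncol(X))   # 100% purity
  # median intra-module correlation comfortably high on planted modules
  knee_row <- mh$cut_stats[mh$cut_stats$cut == "knee", ]
  expect_gte(knee_row$median_intra_correlation, 0.4)
  # cuts nest: labels at D=4 refine labels at D=10
  nests <- function(fine, coarse)
    all(tapply(coarse, fine, function(v) length(unique(v))) == 1L)
  expect_true(nests(mh$cuts$D4, mh$cuts$D10))
  expect_true(nests(mh$cuts$D6, mh$cuts$D10))
  # linkage heights non-decreasing
  expect_true(all(diff(mh$hclust$height) >= -1e-12))
})

test_that("constant genes are dropped from module clustering with a warning", {
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:6)))
  X[, 6] <- 2
  counts <- matrix(1L, n, 6, dimnames = dimnames(X))
  ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE))
  ds$layers$normalized <- X
  expect_warning(mh <- module_hierarchy(ds, colnames(X)), "constant")
  expect_false("g06" %in% mh$genes)
})

test_that("module cell scores are highest in the module's home region", {
  sim <- ref_sim_normalized()
  ds <- sim$dataset
  gt <- sim$model$genes
  fb_genes <- gt$gene_id[gt$template == "fb_front"]
  hb_genes <- gt$gene_id[gt$template == "hb_front"]
  mh <- module_hierarchy(ds, c(fb_genes, hb_genes), cut_distances = c(10))
  sc <- module_cell_scores(ds, mh, cut = "knee")
  # the module containing forebrain genes scores higher in forebrain cells
  fb_mod <- names(which.max(table(mh$knee_labels[mh$genes %in% fb_genes])))
  col <- paste0("module", fb_mod)
  is_fb <- sim$model$cells$region == "forebrain"
  expect_gt(mean(sc[is_fb, col]), mean(sc[!is_fb, col]) + 1)
})
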