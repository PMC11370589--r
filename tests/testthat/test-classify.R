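blob_coords <- function(n_per, centers, sd = 1) {
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
}

test_that("graph clustering separates well-separated blobs perfectly", {
  set.seed(1)
  coords <- blob_coords(200, rbind(c(0, 0), c(40, 0)))  # 20 sd apart
  g <- knn_graph(coords, k = 15L, mode = "unit")
  truth <- rep(0:1, each = 200)
  # at a coarse resolution the two blobs are exactly two pure clusters
  cl <- graph_cluster(g, seed = 0L, resolution = 0.1)
  expect_equal(length(unique(cl)), 2L)
  purity <- max(mean(cl == truth), mean(cl == 1 - truth))
  expect_equal(purity, 1)
  # at the default resolution clusters may subdivide a blob but never mix
  cl1 <- graph_cluster(g, seed = 0L)
  expect_true(all(tapply(truth, cl1, function(v) length(unique(v))) == 1L))
})

test_that("clustering is robust to k (Rand index > 0.8 for k vs k+5)", {
  set.seed(2)
  coords <- blob_coords(150, rbind(c(0, 0), c(12, 0), c(0, 12)), sd = 1.5)
  cl1 <- graph_cluster(knn_graph(coords, k = 15L, mode = "unit"), seed = 0L)
  cl2 <- graph_cluster(knn_graph(coords, k = 20L, mode = "unit"), seed = 0L)
  # Rand index
  same1 <- outer(cl1, cl1, "==")[upper.tri(diag(length(cl1)))]
  same2 <- outer(cl2, cl2, "==")[upper.tri(diag(length(cl2)))]
  ri <- mean(same1 == same2)
  expect_gt(ri, 0.8)
})

test_that("a complete graph is one cluster", {
  W <- Matrix::Matrix(1, 20, 20) - Matrix::Diagonal(20)
  g <- structure(list(weights = as(W, "CsparseMatrix"), k = 19L,
                      mode = "unit", symmetric = TRUE),
                 class = "plate_graph")
  expect_equal(length(unique(graph_cluster(g, seed = 0L))), 1L)
})

test_that("signature score of the all-genes set is zero", {
  sim <- simulate_tissue(sim_config(seed = 2L, n_cells = 60L, n_genes = 50L,
                                    n_ap = 5L, n_ml = 3L, n_both = 0L,
                                    n_time = 2L))
  ds <- normalize_log(sim$dataset)
  gs <- gene_set("all", colnames(ds$counts))
  sc <- signature_score(ds, gs)
  expect_equal(sc$z, rep(0, 60), tolerance = 1e-10)
})

test_that("random-split null signatures score approximately N(0,1)", {
  ds <- simulate_null_matrix(400, 300, seed = 5L)
  ds <- normalize_log(ds)
  set.seed(5)
  # score many disjoint random signatures and pool the z values
  zs <- unlist(lapply(1:12, function(i) {
    genes <- sample(colnames(ds$counts), 20)
    signature_score(ds, gene_set(paste0("s", i), genes[1:10], genes[11:20]))$z
  }))
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(ks.test(zs, "pnorm", mean(zs), sd(zs))$p.value, 0.01)
  expect_true(sd(zs) > 0.8 && sd(zs) < 1.25)
})

test_that("planted marker programs score higher in their target cells", {
  set.seed(6)
  n <- 400
  counts <- matrix(rpois(n * 100, 4), n, 100,
                   dimnames = list(sprintf("c%03d", 1:n), sprintf("g%03d", 1:100)))
  ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE))
  ds <- normalize_log(ds)
  target <- seq_len(n) <= 150
  ds$layers$normalized[target, 1:5] <- ds$layers$normalized[target, 1:5] + 2
  z <- signature_score(ds, gene_set("prog", sprintf("g%03d", 1:5)))$z
  thr <- quantile(z[!target], 0.99)
  expect_gte(mean(z[target] > max(z[!target])), 0.95)
  # with negatives, invariant to adding a constant to all genes of a cell
  gs2 <- gene_set("signed", sprintf("g%03d", 1:5), sprintf("g%03d", 6:10))
  z1 <- signature_score(ds, gs2)$z
  ds$layers$normalized[3, ] <- ds$layers$normalized[3, ] + 7
  z2 <- signature_score(ds, gs2)$z
  expect_equal(z1[3], z2[3], tolerance = 1e-10)
})

test_that("training-set construction follows the 20th-percentile rule", {
  set.seed(7)
  scores <- cbind(A = c(rnorm(50, 3), rnorm(50, -3)),
                  B = c(rnorm(50, -3), rnorm(50, 3)))
  prelim <- rep(c("A", "B"), each = 50)
  lab <- build_training_labels(scores, prelim)
  # perfectly separated: only sub-20th-percentile own-score cells drop
  expect_true(all(is.na(lab[1:50]) | lab[1:50] == "A"))
  expect_gte(sum(lab == "A", na.rm = TRUE), 40 * 0.99)
  expect_gte(sum(lab == "B", na.rm = TRUE), 40 * 0.99)
  # a cell above both thresholds is unlabeled
  scores2 <- scores
  thrA <- quantile(scores[prelim == "A", "A"], 0.2)
  thrB <- quantile(scores[prelim == "B", "B"], 0.2)
  scores2[1, ] <- c(thrA + 1, thrB + 1)
  lab2 <- build_training_labels(scores2, prelim)
  expect_true(is.na(lab2[1]))
  # a cell below its own threshold is unlabeled
  scores3 <- scores
  scores3[2, "A"] <- thrA - 10
  lab3 <- build_training_labels(scores3, prelim)
  expect_true(is.na(lab3[2]))
  # a type with no survivors errors with its name
  scores4 <- scores; scores4[prelim == "B", "B"] <- 0; scores4[, "A"] <- 10
  expect_error(build_training_labels(cbind(A = scores4[, "A"],
                                           B = scores4[, "B"]), prelim),
               "B")
})

test_that("absorption probabilities solve the chain A-u1-u2-B exactly", {
  # 4-node path graph, unit weights, ends absorbing
  W <- Matrix::sparseMatrix(i = c(1, 2, 2, 3, 3, 4),
                            j = c(2, 1, 3, 2, 4, 3), x = 1, dims = c(4, 4))
  g <- structure(list(weights = W, k = 1L, mode = "unit", symmetric = TRUE),
                 class = "plate_graph")
  res <- absorption_classify(g, c("A", NA, NA, "B"))
  expect_equal(unname(res$absorption[2, ]), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(unname(res$absorption[3, ]), c(1 / 3, 2 / 3), tolerance = 1e-10)
  expect_equal(res$assigned, c("A", "A", "B", "B"))
})

test_that("one-step absorption: all-training neighborhoods give probability 1", {
  W <- Matrix::sparseMatrix(i = c(1, 1, 2, 3), j = c(2, 3, 1, 1), x = 1,
                            dims = c(3, 3))
  W <- (W + Matrix::t(W))
  g <- structure(list(weights = W, k = 2L, mode = "unit", symmetric = TRUE),
                 class = "plate_graph")
  res <- absorption_classify(g, c(NA, "A", "A"))
  expect_equal(unname(res$absorption[1, "A"]), 1, tolerance = 1e-12)
})

test_that("absorption matches a dense linear-solve oracle and is scale invariant", {
  set.seed(8)
  n <- 150
  coords <- matrix(rnorm(n * 2), n, 2)
  g <- knn_graph(coords, k = 8L, mode = "adaptive_gaussian")
  labels <- rep(NA_character_, n)
  labels[1:10] <- "A"; labels[11:20] <- "B"; labels[21:25] <- "C"
  res <- absorption_classify(g, labels)
  expect_true(all(abs(rowSums(res$absorption) - 1) < 1e-8))
  # dense oracle
  P <- as.matrix(g$weights) / rowSums(as.matrix(g$weights))
  U <- which(is.na(labels)); L <- which(!is.na(labels))
  ind <- model.matrix(~ 0 + factor(labels[L]))
  B0 <- solve(diag(length(U)) - P[U, U], P[U, L] %*% ind)
  expect_lt(max(abs(res$absorption[U, ] - B0)), 1e-6)
  # invariance to graph weight rescaling
  g2 <- g; g2$weights <- g$weights * 37
  res2 <- absorption_classify(g2, labels)
  expect_equal(res$absorption, res2$absorption, tolerance = 1e-10)
})

test_that("region assignment recovers the four ground-truth domains", {
  sim <- ref_sim_normalized()
  sets <- ground_truth_gene_sets(sim$model)
  ds <- suppressWarnings(assign_regions(sim$dataset, sets, seed = 0L))
  acc <- mean(ds$cells$region == sim$model$cells$region)
  expect_gte(acc, 0.95)
  # missing marker genes for one region error out in training construction
  sets$midline <- gene_set("midline", c("absent1", "absent2"))
  expect_error(suppressWarnings(assign_regions(sim$dataset, sets, seed = 0L)))
})
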