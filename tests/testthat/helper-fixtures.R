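# Shared fixtures, computed lazily and cached for the session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The reference tissue: 2,000 cells, 500 genes, 60 AP / 40 ML / 20 both /
# 30 time patterned genes, seed 1.
ref_sim <- function() cached("ref_sim", simulate_tissue(sim_config(seed = 1L)))

ref_sim_normalized <- function() cached("ref_sim_norm", {
  sim <- ref_sim()
  sim$dataset <- normalize_log(sim$dataset)
  sim
})

# Reference tissue restricted to the two latest stages (spatial axes are
# computed on pooled late-stage cells, as temporal variation blurs them).
ref_late <- function() cached("ref_late", {
  sim <- ref_sim()
  late <- sim$model$cells$stage >= 4
  ds <- normalize_log(subset_dataset(sim$dataset, cell_mask = late))
  list(dataset = ds, cells = sim$model$cells[late, ], genes = sim$model$genes)
})

# Diffusion map of the late-stage reference tissue.
ref_late_diffusion <- function() cached("ref_late_dm", {
  fix <- ref_late()
  hv <- suppressWarnings(select_hvg(fix$dataset, n_top = 3000L))
  pca <- pca_to_variance(fix$dataset, hvg = hv)
  g <- knn_graph(pca, k = 30L, mode = "adaptive_gaussian")
  dm <- diffusion_map(g, n_components = 40L)
  list(dm = dm, pca = pca, fix = fix)
})

# Truly spatially patterned gene ids of the reference model.
spatial_truth_genes <- function(model) {
  model$genes$gene_id[model$genes$axis %in% c("AP", "ML", "both")]
}

# A small toy 10x-style triplet on disk; counts given genes x cells.
write_toy_triplet <- function(dir, counts_gc, barcodes, features) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts_gc, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(features, file.path(dir, "features.tsv"))
  dir
}
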