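#' @importFrom Matrix readMM writeMM colSums rowSums t sparseMatrix Diagonal crossprod
#' @importFrom methods as is
#' @importFrom stats median var sd density p.adjust pnorm pchisq pt cor
#' @importFrom utils read.delim write.table head
NULL

# Default gene-symbol prefixes for mitochondrial and ribosomal genes (mouse
# conventions); both matched case-insensitively at the start of the symbol.
MITO_PREFIXES <- c("mt-")
RIBO_PREFIXES <- c("Rps", "Rpl")

#' Construct a single-cell dataset container
#'
#' The central container of the package: a sparse cells x genes UMI count
#' matrix plus per-cell and per-gene metadata, named expression layers
#' (e.g. \code{"normalized"}, \code{"imputed"}), named embeddings and named
#' neighbor graphs. Counts are stored cells x genes in memory; the 10x disk
#' convention (genes x cells) is transposed on load by [load_mtx()].
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#'   (coerced to a sparse \code{dgCMatrix}); dimnames give cell and gene ids.
#' @param cells optional data.frame of per-cell metadata with a
#'   \code{cell_id} column; derived statistics are (re)computed from counts.
#' @param genes optional data.frame of per-gene metadata with a
#'   \code{gene_id} column.
#' @param mito_prefixes,ribo_prefixes gene-symbol prefixes used to flag
#'   mitochondrial and ribosomal genes (case-insensitive).
#' @return An object of class \code{plate_dataset} with elements
#'   \code{counts}, \code{layers}, \code{cells}, \code{genes},
#'   \code{embeddings}, \code{graphs}.
#' @export
new_dataset <- function(counts, cells = NULL, genes = NULL,
                        mito_prefixes = MITO_PREFIXES,
                        ribo_prefixes = RIBO_PREFIXES) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0)) stop("counts contain negative entries")
  if (any(counts@x != round(counts@x))) stop("counts contain non-integer values")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene%05d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")

  if (is.null(cells)) {
    cells <- data.frame(cell_id = rownames(counts), stringsAsFactors = FALSE)
  } else {
    stopifnot(identical(cells$cell_id, rownames(counts)))
  }
  if (is.null(genes)) {
    genes <- data.frame(gene_id = colnames(counts), stringsAsFactors = FALSE)
  } else {
    stopifnot(identical(genes$gene_id, colnames(counts)))
  }
  ds <- structure(
    list(counts = counts, layers = list(), cells = cells, genes = genes,
         embeddings = list(), graphs = list()),
    class = "plate_dataset")
  recompute_stats(ds, mito_prefixes = mito_prefixes,
                  ribo_prefixes = ribo_prefixes)
}

match_prefix <- function(ids, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(ids)))
  pat <- paste0("^(", paste(vapply(prefixes, function(p)
    gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", p), ""), collapse = "|"), ")")
  grepl(pat, ids, ignore.case = TRUE)
}

#' Recompute derived per-cell and per-gene statistics from counts
#'
#' Fills \code{total_umis}, \code{n_genes_detected}, \code{pct_mito},
#' \code{pct_ribo} in the cell table and \code{n_cells_expressing},
#' \code{is_mito}, \code{is_ribo} in the gene table. Always derived from the
#' raw counts, so the invariant "derived statistics equal recomputation"
#' holds by construction.
#'
#' @param ds a \code{plate_dataset}
#' @inheritParams new_dataset
#' @return the dataset with refreshed metadata
#' @export
recompute_stats <- function(ds, mito_prefixes = MITO_PREFIXES,
                            ribo_prefixes = RIBO_PREFIXES) {
  counts <- ds$counts
  is_mito <- match_prefix(colnames(counts), mito_prefixes)
  is_ribo <- match_prefix(colnames(counts), ribo_prefixes) & !is_mito
  tot <- Matrix::rowSums(counts)
  ds$cells$total_umis <- as.integer(round(tot))
  ds$cells$n_genes_detected <- as.integer(Matrix::rowSums(counts > 0))
  safe_tot <- ifelse(tot > 0, tot, 1)
  ds$cells$pct_mito <- as.numeric(Matrix::rowSums(counts[, is_mito, drop = FALSE]) / safe_tot)
  ds$cells$pct_ribo <- as.numeric(Matrix::rowSums(counts[, is_ribo, drop = FALSE]) / safe_tot)
  if (is.null(ds$cells$quality_class)) ds$cells$quality_class <- "unset"
  ds$genes$n_cells_expressing <- as.integer(Matrix::colSums(counts > 0))
  ds$genes$is_mito <- is_mito
  ds$genes$is_ribo <- is_ribo
  if (is.null(ds$genes$is_curated_marker))
    ds$genes$is_curated_marker <- FALSE
  ds
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("<plate_dataset> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if (length(x$layers)) cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (length(x$embeddings)) cat("  embeddings:", paste(names(x$embeddings), collapse = ", "), "\n")
  if (length(x$graphs)) cat("  graphs:", paste(names(x$graphs), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.plate_dataset <- function(x) dim(x$counts)

#' Load a 10x-style MatrixMarket triplet directory
#'
#' Reads \code{matrix.mtx} (genes x cells on disk, transposed on load),
#' \code{barcodes.tsv} (one cell id per line) and \code{features.tsv}
#' (gene id in the first column), and populates derived cell and gene
#' statistics.
#'
#' @param dir_path directory containing the triplet
#' @inheritParams new_dataset
#' @return a \code{plate_dataset}
#' @export
load_mtx <- function(dir_path, mito_prefixes = MITO_PREFIXES,
                     ribo_prefixes = RIBO_PREFIXES) {
  mtx <- file.path(dir_path, "matrix.mtx")
  bc <- file.path(dir_path, "barcodes.tsv")
  ft <- file.path(dir_path, "features.tsv")
  for (f in c(mtx, bc, ft))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(bc)
  features <- read.delim(ft, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix has %d columns but barcodes file has %d rows",
                 ncol(m), length(barcodes)))
  if (nrow(m) != length(features))
    stop(sprintf("matrix has %d rows but features file has %d rows",
                 nrow(m), length(features)))
  m <- Matrix::t(m)                      # disk: genes x cells -> memory: cells x genes
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  if (length(m@x) && any(m@x != round(m@x)))
    stop("matrix contains non-integer values")
  dimnames(m) <- list(barcodes, features)
  new_dataset(m, mito_prefixes = mito_prefixes, ribo_prefixes = ribo_prefixes)
}

#' Write a dataset as a 10x-style MatrixMarket triplet
#'
#' @param ds a \code{plate_dataset}
#' @param dir_path output directory (created if absent)
#' @export
save_mtx <- function(ds, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir_path, "matrix.mtx"))
  writeLines(rownames(ds$counts), file.path(dir_path, "barcodes.tsv"))
  write.table(data.frame(colnames(ds$counts)),
              file.path(dir_path, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}

#' Save / load a dataset to a single hierarchical container file
#'
#' The container is a single-file R serialization of the full object tree
#' (counts, layers, metadata tables, embeddings, graphs), versioned with a
#' magic header so corrupt or foreign files fail loudly rather than load
#' partially. Round-trips are exact for counts and full-precision for reals.
#'
#' @param ds a \code{plate_dataset}
#' @param path file path
#' @return \code{load_dataset} returns the restored \code{plate_dataset}.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "plate_dataset"))
  obj <- list(magic = "plate_dataset_container", version = 1L, payload = ds)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable container: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$magic, "plate_dataset_container"))
    stop("not a plate_dataset container: ", path)
  obj$payload
}

#' Parse a tab-delimited gene-set file
#'
#' One set per row: name, comma-separated positive genes, optional
#' comma-separated negative genes. Genes absent from a dataset are dropped
#' at scoring time (with a warning), not at parse time.
#'
#' @param path gene-set file
#' @return list of \code{gene_set} objects (name, positive_genes,
#'   negative_genes)
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("gene-set row needs at least name and positive genes: ", ln)
    pos <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    pos <- pos[nzchar(pos)]
    neg <- if (length(parts) >= 3L) {
      n <- trimws(strsplit(parts[3], ",", fixed = TRUE)[[1]]); n[nzchar(n)]
    } else character(0)
    gene_set(trimws(parts[1]), pos, neg)
  })
  nm <- vapply(sets, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("duplicate gene-set names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  sets
}

#' Construct a gene set (signature)
#'
#' @param name set name
#' @param positive_genes non-empty character vector of positive markers
#' @param negative_genes optional negative markers, disjoint from positives
#' @return object of class \code{gene_set}
#' @export
gene_set <- function(name, positive_genes, negative_genes = character(0)) {
  if (length(positive_genes) == 0L)
    stop("gene set '", name, "' has an empty positive list")
  overlap <- intersect(positive_genes, negative_genes)
  if (length(overlap))
    stop("gene set '", name, "' has genes in both lists: ",
         paste(overlap, collapse = ", "))
  structure(list(name = name,
                 positive_genes = unique(positive_genes),
                 negative_genes = unique(negative_genes)),
            class = "gene_set")
}

#' Subset a dataset by cell and/or gene masks
#'
#' Counts, layers and metadata are subset consistently; derived statistics
#' are recomputed. Embeddings and graphs are dropped: geometry must be
#' recomputed on a subset (normalization and graphs are sample-set
#' dependent), which prevents stale-geometry bugs.
#'
#' @param ds a \code{plate_dataset}
#' @param cell_mask logical vector over cells (default all)
#' @param gene_mask logical vector over genes (default all)
#' @return the subset \code{plate_dataset}
#' @export
subset_dataset <- function(ds, cell_mask = NULL, gene_mask = NULL) {
  n <- nrow(ds$counts); g <- ncol(ds$counts)
  if (is.null(cell_mask)) cell_mask <- rep(TRUE, n)
  if (is.null(gene_mask)) gene_mask <- rep(TRUE, g)
  stopifnot(is.logical(cell_mask), length(cell_mask) == n,
            is.logical(gene_mask), length(gene_mask) == g)
  if (!any(cell_mask)) stop("cell mask removes every cell")
  if (!any(gene_mask)) stop("gene mask removes every gene")
  out <- ds
  out$counts <- ds$counts[cell_mask, gene_mask, drop = FALSE]
  out$layers <- lapply(ds$layers, function(l) l[cell_mask, gene_mask, drop = FALSE])
  out$cells <- ds$cells[cell_mask, , drop = FALSE]
  rownames(out$cells) <- NULL
  out$genes <- ds$genes[gene_mask, , drop = FALSE]
  rownames(out$genes) <- NULL
  out$embeddings <- list()
  out$graphs <- list()
  recompute_stats(out)
}
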