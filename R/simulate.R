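#' Simulation configuration for synthetic cranial neural plate tissue
#'
#' The generator emulates the structure of a droplet scRNA-seq study of the
#' embryonic mouse cranial neural plate: cells carry latent
#' anterior-posterior (AP), mediolateral (ML) and temporal coordinates;
#' genes are patterned along these axes by smooth templates (logistic fronts
#' and bands along AP, monotone gradients and midline Gaussian bumps along
#' ML, monotone ramps along time); counts are negative binomial with
#' log-normal library-size variation; an optional low-quality cell mode has
#' reduced library size, boosted mitochondrial fraction, and expression
#' collapsed toward a few dominant genes; an optional treatment expands the
#' medial program at the expense of the lateral one.
#'
#' @param seed integer seed; all randomness is derived from it.
#' @param n_cells,n_genes dataset dimensions.
#' @param n_ap,n_ml,n_both,n_time counts of genes patterned along AP only,
#'   ML only, both spatial axes, and time; the remainder (minus housekeeping
#'   mito/ribo genes) are unpatterned nulls.
#' @param amplitude multiplicative amplitude of patterned templates: a
#'   gene's rate varies by a factor of \code{1 + amplitude} across its axis.
#' @param dispersion negative binomial dispersion (1/size); 0.3 is typical
#'   droplet overdispersion.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param n_stages number of somite-stage bins (stage index 0..n_stages-1).
#' @param low_quality_fraction fraction of cells drawn from the low-quality
#'   mode.
#' @param low_quality_libsize_factor multiplier (<1) on low-quality library
#'   size.
#' @param low_quality_mito_boost multiplier on mitochondrial rates in
#'   low-quality cells.
#' @param low_quality_collapse fraction of a low-quality cell's rate mass
#'   reassigned to its 50 highest-rate genes (emulating one predominant
#'   gene program).
#' @param nonneural_fraction fraction of cells given a non-neural
#'   (contaminating) cell type with its own marker program.
#' @param treatment_effect fold-change applied by
#'   [simulate_treatment_pair()] to medial-program genes (and, inverted, to
#'   lateral-program genes).
#' @param treatment_regions regions in which the treatment acts.
#' @param n_mito,n_ribo numbers of housekeeping mitochondrial / ribosomal
#'   genes (named with "mt-" / "Rps" prefixes), taken from the null pool.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_cells = 2000L, n_genes = 500L,
                       n_ap = 60L, n_ml = 40L, n_both = 20L, n_time = 30L,
                       amplitude = 3, dispersion = 0.3,
                       libsize_meanlog = log(5000), libsize_sdlog = 0.25,
                       n_stages = 6L,
                       low_quality_fraction = 0,
                       low_quality_libsize_factor = 0.25,
                       low_quality_mito_boost = 3,
                       low_quality_collapse = 0.8,
                       nonneural_fraction = 0,
                       treatment_effect = 2,
                       treatment_regions = c("forebrain", "midbrain_r1", "hindbrain"),
                       n_mito = 10L, n_ribo = 10L) {
  cfg <- as.list(environment())
  n_pat <- n_ap + n_ml + n_both + n_time
  if (n_pat + n_mito + n_ribo > n_genes)
    stop("gene-category counts (", n_pat + n_mito + n_ribo,
         ") exceed n_genes (", n_genes, ")")
  stopifnot(low_quality_fraction >= 0, low_quality_fraction <= 1,
            nonneural_fraction >= 0, nonneural_fraction <= 1,
            dispersion > 0)
  class(cfg) <- "sim_config"
  cfg
}

# Region from latent coordinates: fixed AP breakpoints, midline overrides.
region_from_coords <- function(ap, ml) {
  region <- ifelse(ap < 0.33, "forebrain",
                   ifelse(ap < 0.66, "midbrain_r1", "hindbrain"))
  region[ml < 0.08] <- "midline"
  region
}

# Draw the gene program: per-gene template family and parameters plus
# baselines. Drawn once per model so that paired conditions share it
# exactly; rate evaluation on a set of cells is then deterministic.
draw_gene_model <- function(cfg) {
  n_genes <- cfg$n_genes
  idx <- 0L
  gene_tab <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    axis = "null", template = "flat", amplitude = 0,
    program = "none", stringsAsFactors = FALSE)
  par_center <- rep(NA_real_, n_genes)
  par_sharp <- rep(NA_real_, n_genes)
  par_sign <- rep(NA_real_, n_genes)
  par_mldir <- rep(NA_real_, n_genes)

  take <- function(n) { i <- idx + seq_len(n); idx <<- idx + n; i }

  # AP genes: cycle forebrain front / midbrain-r1 band / hindbrain front /
  # generic logistic fronts at random positions, so cluster-like gene
  # groups exist by construction at the region breakpoints.
  ap_idx <- take(cfg$n_ap)
  for (j in seq_along(ap_idx)) {
    g <- ap_idx[j]
    kind <- (j - 1L) %% 4L
    gene_tab$axis[g] <- "AP"
    gene_tab$template[g] <- c("fb_front", "mb_band", "hb_front", "free_front")[kind + 1L]
    if (kind == 3L) {
      par_center[g] <- stats::runif(1, 0.15, 0.85)
      par_sign[g] <- sample(c(-1, 1), 1)
      par_sharp[g] <- 0.05
    }
  }

  # ML genes: alternate medial gradient (high at midline), lateral
  # gradient, and a near-binary floor-plate-like midline marker.
  # Medial/lateral membership defines the treatment programs.
  ml_idx <- take(cfg$n_ml)
  for (j in seq_along(ml_idx)) {
    g <- ml_idx[j]
    kind <- (j - 1L) %% 3L
    gene_tab$axis[g] <- "ML"
    gene_tab$template[g] <- c("medial_gradient", "lateral_gradient", "midline_bump")[kind + 1L]
    gene_tab$program[g] <- c("medial", "lateral", "medial")[kind + 1L]
  }

  # Both-axes genes: product of an AP front and an ML gradient.
  both_idx <- take(cfg$n_both)
  for (j in seq_along(both_idx)) {
    g <- both_idx[j]
    gene_tab$axis[g] <- "both"
    gene_tab$template[g] <- "front_x_gradient"
    par_center[g] <- sample(c(0.33, 0.66), 1)
    par_sign[g] <- sample(c(-1, 1), 1)
    par_sharp[g] <- 0.06
    par_mldir[g] <- if (j %% 2L == 0L) 1 else -1   # lateral- or medial-high
  }

  # Temporal genes: monotone ramps up or down in stage time.
  time_idx <- take(cfg$n_time)
  for (j in seq_along(time_idx)) {
    g <- time_idx[j]
    gene_tab$axis[g] <- "time"
    gene_tab$template[g] <- if (j %% 2L == 0L) "ramp_up" else "ramp_down"
  }

  amp <- rep(0, n_genes)
  amp[seq_len(idx)] <- cfg$amplitude
  # midline markers are effectively on/off in vivo; double their amplitude
  amp[gene_tab$template == "midline_bump"] <- 2 * cfg$amplitude
  gene_tab$amplitude <- amp

  # Housekeeping mito/ribo genes come out of the null pool.
  null_idx <- setdiff(seq_len(n_genes), seq_len(idx))
  mito_idx <- null_idx[seq_len(cfg$n_mito)]
  ribo_idx <- null_idx[cfg$n_mito + seq_len(cfg$n_ribo)]
  gene_tab$gene_id[mito_idx] <- sprintf("mt-sim%02d", seq_along(mito_idx))
  gene_tab$gene_id[ribo_idx] <- sprintf("Rps-sim%02d", seq_along(ribo_idx))
  gene_tab$axis[c(mito_idx, ribo_idx)] <- "housekeeping"

  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.8)  # abundances span orders of magnitude
  baseline[mito_idx] <- baseline[mito_idx] * 3   # mito genes are abundant

  pool <- setdiff(null_idx, c(mito_idx, ribo_idx))
  marker_idx <- pool[seq_len(min(10L, length(pool)))]

  list(gene_tab = gene_tab, baseline = baseline,
       par_center = par_center, par_sharp = par_sharp, par_sign = par_sign,
       par_mldir = par_mldir,
       mito_idx = mito_idx, ribo_idx = ribo_idx, marker_idx = marker_idx)
}

# Evaluate the cells x genes relative-rate matrix of a drawn gene model at
# given latent coordinates. Deterministic. Templates are in [0,1]; a
# gene'"'"'s rate is baseline * (1 + amplitude * template).
eval_rates <- function(gm, cfg, ap, ml, tm, nonneural = NULL) {
  n_cells <- length(ap)
  if (is.null(nonneural)) nonneural <- rep(FALSE, n_cells)
  logistic <- function(x, c0, s, sign) stats::plogis(sign * (x - c0) / s)
  gt <- gm$gene_tab
  tpl_mat <- matrix(0, n_cells, cfg$n_genes)
  for (g in which(gt$amplitude > 0)) {
    tpl_mat[, g] <- switch(gt$template[g],
      fb_front = logistic(ap, 0.33, 0.03, -1),
      mb_band = logistic(ap, 0.33, 0.03, 1) * logistic(ap, 0.66, 0.03, -1),
      hb_front = logistic(ap, 0.66, 0.03, 1),
      free_front = logistic(ap, gm$par_center[g], gm$par_sharp[g], gm$par_sign[g]),
      medial_gradient = 1 - ml,
      lateral_gradient = ml,
      midline_bump = logistic(ml, 0.08, 0.01, -1),  # floor-plate-like, near-binary
      front_x_gradient = logistic(ap, gm$par_center[g], gm$par_sharp[g], gm$par_sign[g]) *
        (if (gm$par_mldir[g] > 0) ml else 1 - ml),
      ramp_up = tm,
      ramp_down = 1 - tm,
      0)
  }
  rate <- sweep(1 + sweep(tpl_mat, 2, gt$amplitude, `*`), 2, gm$baseline, `*`)
  if (any(nonneural)) {
    # non-neural cells: flat on neural programs, strong on their own markers
    pat <- which(gt$amplitude > 0)
    rate[nonneural, pat] <- rep(gm$baseline[pat], each = sum(nonneural))
    rate[nonneural, gm$marker_idx] <- rate[nonneural, gm$marker_idx] * (1 + cfg$amplitude * 2)
  }
  rate
}

# Sample NB counts given per-cell library sizes and a relative-rate matrix.
sample_counts <- function(rate, libsize, dispersion) {
  rel <- rate / rowSums(rate)
  mu <- rel * libsize
  n <- length(mu)
  cnt <- stats::rnbinom(n, size = 1 / dispersion, mu = as.vector(mu))
  matrix(cnt, nrow = nrow(rate), ncol = ncol(rate))
}

#' Simulate a ground-truthed synthetic neural plate tissue
#'
#' @param cfg a [sim_config()]
#' @return list with \code{dataset} (a \code{plate_dataset}) and
#'   \code{model}: ground truth with \code{cells} (ap/ml/time coordinates,
#'   region, low-quality and non-neural flags) and \code{genes} (axis,
#'   template, amplitude, program). Ground truth is a sidecar — nothing the
#'   pipeline reads.
#' @export
simulate_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  ap <- stats::runif(n)
  ml <- stats::runif(n)
  stage <- sample(0:(cfg$n_stages - 1L), n, replace = TRUE)
  tm <- stage / max(1L, cfg$n_stages - 1L)
  region <- region_from_coords(ap, ml)
  n_low <- round(cfg$low_quality_fraction * n)
  low <- rep(FALSE, n); if (n_low > 0) low[sample(n, n_low)] <- TRUE
  n_non <- round(cfg$nonneural_fraction * n)
  nonneural <- rep(FALSE, n)
  if (n_non > 0) nonneural[sample(which(!low), n_non)] <- TRUE

  mod <- draw_gene_model(cfg)
  if (any(nonneural)) mod$gene_tab$axis[mod$marker_idx] <- "nonneural_marker"
  rate <- eval_rates(mod, cfg, ap, ml, tm, nonneural)
  libsize <- stats::rlnorm(n, cfg$libsize_meanlog, cfg$libsize_sdlog)

  if (any(low)) {
    libsize[low] <- libsize[low] * cfg$low_quality_libsize_factor
    rate[low, mod$mito_idx] <- rate[low, mod$mito_idx] * cfg$low_quality_mito_boost
    # collapse expression toward the 50 highest-rate genes
    mean_rate <- colMeans(rate)
    top50 <- order(mean_rate, decreasing = TRUE)[seq_len(min(50L, ncol(rate)))]
    lam <- cfg$low_quality_collapse
    rl <- rate[low, , drop = FALSE]
    mass <- rowSums(rl)
    rl <- rl * (1 - lam)
    w <- mean_rate[top50] / sum(mean_rate[top50])
    rl[, top50] <- rl[, top50] + lam * outer(mass, w)
    rate[low, ] <- rl
  }

  counts <- sample_counts(rate, libsize, cfg$dispersion)
  dimnames(counts) <- list(sprintf("cell%05d", seq_len(n)), mod$gene_tab$gene_id)

  stage_labels <- c("0 somites", "1-2 somites", "3 somites",
                    "4-6 somites", "7-9 somites", "10+ somites")
  cells <- data.frame(
    cell_id = rownames(counts),
    replicate_id = sprintf("rep%d", 1L + (seq_len(n) %% 3L)),
    stage_label = stage_labels[pmin(stage, 5L) + 1L],
    stage_index = stage,
    treatment = "unset",
    stringsAsFactors = FALSE)
  ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE), cells = cells)

  model <- list(
    cells = data.frame(
      cell_id = rownames(counts), ap = ap, ml = ml, time = tm,
      stage = stage, region = region, is_low_quality = low,
      is_nonneural = nonneural, stringsAsFactors = FALSE),
    genes = mod$gene_tab,
    config = cfg)
  list(dataset = ds, model = model)
}

#' Simulate a control/treated dataset pair with a known regional effect
#'
#' The treated dataset multiplies medial-program gene rates by
#' \code{treatment_effect} and divides lateral-program gene rates by it, in
#' the configured regions only. Cells are drawn independently for the two
#' conditions (two embryo pools); the gene program table is shared, and the
#' ground truth records per-region log2 fold changes of the perturbed genes.
#'
#' @param cfg a [sim_config()] with \code{treatment_effect > 1} (use 1 for a
#'   null pair)
#' @return list with \code{control}, \code{treated} (datasets) and
#'   \code{model}; \code{model$de_truth} lists each perturbed gene with its
#'   program and true per-region log2 fold change.
#' @export
simulate_treatment_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$treatment_effect >= 1)
  set.seed(cfg$seed)
  gm <- draw_gene_model(cfg)          # one shared gene model for both arms
  sim_one <- function(seed_offset, treated) {
    set.seed(cfg$seed + seed_offset)
    n <- cfg$n_cells
    ap <- stats::runif(n); ml <- stats::runif(n)
    stage <- sample(0:(cfg$n_stages - 1L), n, replace = TRUE)
    tm <- stage / max(1L, cfg$n_stages - 1L)
    region <- region_from_coords(ap, ml)
    rate <- eval_rates(gm, cfg, ap, ml, tm)
    if (treated && cfg$treatment_effect > 1) {
      aff <- region %in% cfg$treatment_regions
      med <- gm$gene_tab$program == "medial"
      lat <- gm$gene_tab$program == "lateral"
      rate[aff, med] <- rate[aff, med] * cfg$treatment_effect
      rate[aff, lat] <- rate[aff, lat] / cfg$treatment_effect
    }
    libsize <- stats::rlnorm(n, cfg$libsize_meanlog, cfg$libsize_sdlog)
    counts <- sample_counts(rate, libsize, cfg$dispersion)
    pre <- if (treated) "t" else "c"
    dimnames(counts) <- list(sprintf("%scell%05d", pre, seq_len(n)),
                             gm$gene_tab$gene_id)
    cells <- data.frame(
      cell_id = rownames(counts),
      replicate_id = sprintf("rep%d", 1L + (seq_len(n) %% 3L)),
      stage_label = "7-9 somites", stage_index = stage,
      treatment = if (treated) "treated" else "control",
      stringsAsFactors = FALSE)
    ds <- new_dataset(Matrix::Matrix(counts, sparse = TRUE), cells = cells)
    list(ds = ds, gene_tab = gm$gene_tab,
         truth_cells = data.frame(cell_id = rownames(counts), ap = ap, ml = ml,
                                  region = region, stringsAsFactors = FALSE))
  }
  ctrl <- sim_one(0L, FALSE)
  trt <- sim_one(1000L, TRUE)

  gt <- ctrl$gene_tab
  pert <- gt$program %in% c("medial", "lateral")
  lfc <- ifelse(gt$program == "medial", log2(cfg$treatment_effect),
                ifelse(gt$program == "lateral", -log2(cfg$treatment_effect), 0))
  de_truth <- data.frame(gene_id = gt$gene_id[pert],
                         program = gt$program[pert],
                         log2fc = lfc[pert], stringsAsFactors = FALSE)
  de_truth <- merge(de_truth,
                    expand.grid(gene_id = gt$gene_id[pert],
                                region = cfg$treatment_regions,
                                stringsAsFactors = FALSE),
                    by = "gene_id")
  list(control = ctrl$ds, treated = trt$ds,
       model = list(genes = gt, de_truth = de_truth,
                    control_cells = ctrl$truth_cells,
                    treated_cells = trt$truth_cells,
                    config = cfg))
}

#' Simulate an unstructured null count matrix
#'
#' i.i.d. negative binomial counts with no spatial, temporal or cell-type
#' structure; the oracle input for type-I-error and z-calibration tests.
#'
#' @param n_cells,n_genes dimensions (n_cells must exceed typical graph k)
#' @param seed integer seed
#' @param mean_count per-gene NB mean
#' @param dispersion NB dispersion (1/size)
#' @return a \code{plate_dataset}
#' @export
simulate_null_matrix <- function(n_cells, n_genes, seed = 1L,
                                 mean_count = 5, dispersion = 0.3) {
  if (n_cells < 2L) stop("need at least 2 cells (graph stages need >= k+1)")
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_cells * n_genes, size = 1 / dispersion,
                                  mu = mean_count),
                   nrow = n_cells,
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                   sprintf("gene%04d", seq_len(n_genes))))
  new_dataset(Matrix::Matrix(counts, sparse = TRUE))
}

#' Ground-truth region marker gene sets from a simulated tissue model
#'
#' Returns one signature per region (forebrain, midbrain/r1, hindbrain,
#' midline), built from the generator's template assignments: the first few
#' genes of each region-specific template family.
#'
#' @param model the \code{model} element returned by [simulate_tissue()]
#' @param n_markers markers per region
#' @return named list of \code{gene_set} objects
#' @export
ground_truth_gene_sets <- function(model, n_markers = 5L) {
  gt <- model$genes
  pick <- function(tpl) head(gt$gene_id[gt$template == tpl], n_markers)
  list(
    forebrain = gene_set("forebrain", pick("fb_front")),
    midbrain_r1 = gene_set("midbrain_r1", pick("mb_band")),
    hindbrain = gene_set("hindbrain", pick("hb_front")),
    midline = gene_set("midline", pick("midline_bump")))
}
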