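# Two-part hurdle differential expression.
#
# Expression enters on the log2(median-normalized + 1) scale, with the
# median library size computed jointly over the two groups so the scales
# are comparable.

log2_normalized <- function(counts_a, counts_b) {
  lib_a <- Matrix::rowSums(counts_a)
  lib_b <- Matrix::rowSums(counts_b)
  med <- stats::median(c(lib_a, lib_b))
  A <- log2(1 + as.matrix(Matrix::Diagonal(x = med / lib_a) %*% counts_a))
  B <- log2(1 + as.matrix(Matrix::Diagonal(x = med / lib_b) %*% counts_b))
  list(a = A, b = B)
}

# Vectorized two-part test on two dense cells x genes matrices.
# Detection part: likelihood-ratio (G) test of equal detection probability,
# equivalent to the deviance test of the group-indicator logistic model;
# Fisher's exact test replaces it when any expected 2x2 count is below 5.
# Continuous part: Welch t-test on the positive cells' values, skipped when
# either group has < 3 positives. Parts combine by Fisher's method:
# -2(log p_det + log p_cont) ~ chi-square with df = 2 x (parts available).
hurdle_test_matrix <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  pos_a <- A > 0; pos_b <- B > 0
  ka <- colSums(pos_a); kb <- colSums(pos_b)

  # --- detection part ---
  k <- ka + kb; n <- na + nb
  phat <- k / n
  e_a1 <- na * phat; e_b1 <- nb * phat
  e_a0 <- na * (1 - phat); e_b0 <- nb * (1 - phat)
  gterm <- function(obs, exp) ifelse(obs > 0, obs * log(obs / exp), 0)
  G <- 2 * (gterm(ka, e_a1) + gterm(kb, e_b1) +
            gterm(na - ka, e_a0) + gterm(nb - kb, e_b0))
  p_det <- stats::pchisq(pmax(G, 0), df = 1, lower.tail = FALSE)
  have_det <- k > 0 & k < n         # detection varies at all
  need_exact <- have_det & pmin(e_a1, e_b1, e_a0, e_b0) < 5
  for (j in which(need_exact)) {
    tab <- matrix(c(ka[j], na - ka[j], kb[j], nb - kb[j]), 2)
    p_det[j] <- stats::fisher.test(tab)$p.value
  }

  # --- continuous part (positives only), Welch t ---
  s1a <- colSums(A * pos_a); s2a <- colSums(A^2 * pos_a)
  s1b <- colSums(B * pos_b); s2b <- colSums(B^2 * pos_b)
  mu_a <- ifelse(ka > 0, s1a / ka, 0)
  mu_b <- ifelse(kb > 0, s1b / kb, 0)
  va <- ifelse(ka > 1, (s2a - ka * mu_a^2) / (ka - 1), NA)
  vb <- ifelse(kb > 1, (s2b - kb * mu_b^2) / (kb - 1), NA)
  cont_ok <- ka >= 3 & kb >= 3
  se2 <- va / ka + vb / kb
  tstat <- (mu_b - mu_a) / sqrt(se2)
  df_w <- se2^2 / (va^2 / (ka^2 * (ka - 1)) + vb^2 / (kb^2 * (kb - 1)))
  p_cont <- rep(NA_real_, length(ka))
  p_cont[cont_ok] <- 2 * stats::pt(-abs(tstat[cont_ok]), df = df_w[cont_ok])
  p_cont[cont_ok & se2 == 0] <- 1

  # --- combine ---
  have_cont <- !is.na(p_cont)
  p_comb <- rep(NA_real_, length(ka))
  both <- have_det & have_cont
  p_comb[both] <- stats::pchisq(-2 * (log(p_det[both]) + log(p_cont[both])),
                                df = 4, lower.tail = FALSE)
  only_d <- have_det & !have_cont
  p_comb[only_d] <- p_det[only_d]
  only_c <- !have_det & have_cont
  p_comb[only_c] <- p_cont[only_c]

  effect <- (kb / nb) * mu_b - (ka / na) * mu_a
  log2fc <- colMeans(B) - colMeans(A)
  data.frame(gene_id = colnames(A), effect = effect, p = p_comb,
             p_detection = p_det, p_continuous = p_cont,
             log2fc_empirical = log2fc,
             detection_a = ka / na, detection_b = kb / nb,
             stringsAsFactors = FALSE)
}

#' Two-part hurdle test for one gene
#'
#' Tests a gene for differential expression between two datasets with a
#' two-part model: (i) a likelihood-ratio test of equal detection
#' probability (Fisher's exact test when any expected 2x2 count is below
#' 5); (ii) a Welch t-test on the log2 values of the detecting cells
#' (skipped when either group has fewer than 3 positive cells). The parts
#' combine by Fisher's method (chi-square, df = 2 per available part). The
#' hurdle effect is the difference of zero-inflated means
#' pi_b mu_b - pi_a mu_a on the log2 scale — the closed-form analogue of a
#' hurdle-transformed log2 fold change — and the empirical log2 fold change
#' is the difference of all-cell means.
#'
#' @param ds_a,ds_b \code{plate_dataset}s for the two groups (each >= 20
#'   cells); expression is log2(median-normalized + 1) with a joint median
#' @param gene gene id present in both datasets
#' @return one-row data.frame: \code{effect}, \code{p}, the component
#'   p-values, \code{log2fc_empirical}, detection fractions
#' @export
hurdle_test <- function(ds_a, ds_b, gene) {
  if (nrow(ds_a$counts) < 20L || nrow(ds_b$counts) < 20L)
    stop("both groups need >= 20 cells")
  if (!(gene %in% colnames(ds_a$counts)) || !(gene %in% colnames(ds_b$counts)))
    stop("gene not present in both datasets: ", gene)
  common <- intersect(colnames(ds_a$counts), colnames(ds_b$counts))
  nl <- log2_normalized(ds_a$counts[, common, drop = FALSE],
                        ds_b$counts[, common, drop = FALSE])
  res <- hurdle_test_matrix(nl$a[, gene, drop = FALSE],
                            nl$b[, gene, drop = FALSE])
  if (is.na(res$p)) message("both test components skipped for ", gene)
  res
}

#' Region-wise hurdle differential expression with propagation
#'
#' Runs the hurdle test per gene within each region, BH-adjusts p-values
#' within each region across genes, and applies the two-tier calling rule:
#' a (gene, region) pair is \emph{significant} when FDR < \code{fdr_max}
#' and |effect| > \code{effect_min}; a gene significant in at least one
#' region is additionally \emph{propagated} to every region where
#' p < \code{fdr_max} and |effect| > \code{propagate_effect_min}. Genes are
#' also grouped by the combination of regions in which they are called
#' (e.g. "forebrain+hindbrain"). The midline is excluded by default (low
#' cell numbers).
#'
#' @param ds_control,ds_treated \code{plate_dataset}s with \code{region}
#'   cell labels
#' @param regions regions to test
#' @param fdr_max FDR (and propagation p) ceiling, default 0.001
#' @param effect_min hurdle-effect magnitude for significance, default 0.24
#' @param propagate_effect_min effect magnitude for propagation, default
#'   0.10
#' @return a \code{de_result}: \code{table} (per gene x region: effect, p,
#'   fdr, empirical log2FC, direction, significant, propagated),
#'   \code{summary} (up/down counts per region), \code{groups} (per-gene
#'   region-combination of significant/propagated calls)
#' @export
regional_de <- function(ds_control, ds_treated,
                        regions = c("forebrain", "midbrain_r1", "hindbrain"),
                        fdr_max = 0.001, effect_min = 0.24,
                        propagate_effect_min = 0.10) {
  if (is.null(ds_control$cells$region) || is.null(ds_treated$cells$region))
    stop("region labels missing; run assign_regions first")
  common <- intersect(colnames(ds_control$counts), colnames(ds_treated$counts))
  nl <- log2_normalized(ds_control$counts[, common, drop = FALSE],
                        ds_treated$counts[, common, drop = FALSE])
  tabs <- list()
  for (r in regions) {
    ia <- ds_control$cells$region == r
    ib <- ds_treated$cells$region == r
    if (sum(ia) < 20L || sum(ib) < 20L) {
      warning("region ", r, " has fewer than 20 cells in a condition; skipped")
      next
    }
    t0 <- hurdle_test_matrix(nl$a[ia, , drop = FALSE],
                             nl$b[ib, , drop = FALSE])
    t0$region <- r
    t0$fdr <- stats::p.adjust(t0$p, "BH")
    tabs[[r]] <- t0
  }
  if (length(tabs) == 0L) stop("no region had enough cells in both conditions")
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  tab$direction <- ifelse(tab$effect > 0, "up", "down")
  tab$significant <- !is.na(tab$fdr) & tab$fdr < fdr_max &
    abs(tab$effect) > effect_min
  sig_any <- unique(tab$gene_id[tab$significant])
  tab$propagated <- tab$gene_id %in% sig_any & !tab$significant &
    !is.na(tab$p) & tab$p < fdr_max & abs(tab$effect) > propagate_effect_min

  called <- tab[tab$significant | tab$propagated, , drop = FALSE]
  groups <- if (nrow(called)) {
    agg <- tapply(called$region, called$gene_id, function(r)
      paste(regions[regions %in% r], collapse = "+"))
    data.frame(gene_id = names(agg), regions = as.character(agg),
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(0), regions = character(0))

  summary <- do.call(rbind, lapply(names(tabs), function(r) {
    tr <- tab[tab$region == r, ]
    data.frame(region = r,
               n_up = sum(tr$significant & tr$direction == "up"),
               n_down = sum(tr$significant & tr$direction == "down"))
  }))
  structure(list(table = tab, summary = summary, groups = groups,
                 thresholds = list(fdr_max = fdr_max, effect_min = effect_min,
                                   propagate_effect_min = propagate_effect_min)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
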