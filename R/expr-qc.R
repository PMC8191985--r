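# Dual-reference expression QC: count averaging, FPKM filter, logCPM,
# PCA summary, cross-dataset correlation, and a deliberately simple
# Welch-test differential-expression stage so that the pipeline runs end to
# end on synthetic data. This DE stage is a documented internal stand-in for
# a full linear-model fit, not a reimplementation of one.

#' Average counts mapped against the two references
#'
#' Elementwise mean of the counts obtained against the primary reference and
#' the pseudo reference. Averaged counts may be half-integers; downstream
#' stages accept reals.
#'
#' @param counts_ref,counts_pseudo Numeric matrices (genes x samples) with
#'   identical gene and sample sets (any order).
#' @return Matrix in the row/column order of `counts_ref`.
#' @export
average_dual_counts <- function(counts_ref, counts_pseudo) {
  gdiff <- c(setdiff(rownames(counts_ref), rownames(counts_pseudo)),
             setdiff(rownames(counts_pseudo), rownames(counts_ref)))
  if (length(gdiff))
    stop("gene sets differ between matrices: ", paste(gdiff, collapse = ", "))
  sdiff <- c(setdiff(colnames(counts_ref), colnames(counts_pseudo)),
             setdiff(colnames(counts_pseudo), colnames(counts_ref)))
  if (length(sdiff))
    stop("sample sets differ between matrices: ", paste(sdiff, collapse = ", "))
  (counts_ref + counts_pseudo[rownames(counts_ref), colnames(counts_ref)]) / 2
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * library_size[s])` with
#' library size the column sum of `counts`.
#'
#' @param counts Genes x samples matrix.
#' @param lengths Named numeric vector of exonic lengths (bp) covering all
#'   genes in `counts`.
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, lengths) {
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) stop("missing gene length(s): ", paste(miss, collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len < 1)) stop("gene lengths must be >= 1")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  counts * 1e9 / outer(len, lib)
}

#' Remove lowly expressed genes
#'
#' Keeps a gene iff its mean FPKM is at least `min_fpkm` (inclusive) within
#' at least one sample group. Idempotent; output genes are a subset of input.
#'
#' @inheritParams fpkm
#' @param groups Character vector of group labels, one per sample (column).
#' @param min_fpkm Threshold (default 0.5).
#' @return Filtered counts matrix.
#' @export
filter_low_expression <- function(counts, lengths, groups, min_fpkm = 0.5) {
  stopifnot(length(groups) == ncol(counts))
  f <- fpkm(counts, lengths)
  group_means <- vapply(unique(groups), function(g)
    rowMeans(f[, groups == g, drop = FALSE]), numeric(nrow(counts)))
  keep <- apply(matrix(group_means, nrow = nrow(counts)), 1,
                function(x) any(x >= min_fpkm))
  counts[keep, , drop = FALSE]
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)` with a
#' pseudo-count `prior` (default 0.5) stabilising zeros.
#'
#' @inheritParams fpkm
#' @param prior Positive pseudo-count.
#' @return logCPM matrix.
#' @export
log_cpm <- function(counts, prior = 0.5) {
  stopifnot(prior > 0)
  lib <- colSums(counts)
  t(log2(t(counts + prior) / (lib + 2 * prior) * 1e6))
}

#' PCA summary of an expression matrix
#'
#' Samples are observations; genes are centered and unit-scaled after
#' dropping zero-variance genes. Proportions of variance sum to 1.
#'
#' @param logcpm Genes x samples matrix.
#' @return List: `proportions` (per PC), `projections` (samples x PCs),
#'   `n_genes_used`.
#' @export
pca_summary <- function(logcpm) {
  if (ncol(logcpm) < 2) stop("PCA needs at least 2 samples")
  x <- t(logcpm)
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) == 0) stop("no genes with non-zero variance")
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  prop <- fit$sdev^2 / sum(fit$sdev^2)
  list(proportions = prop, projections = fit$x, n_genes_used = ncol(x))
}

#' Pearson correlation of per-gene mean logCPM between two datasets
#'
#' @param mean_logcpm_a,mean_logcpm_b Named per-gene vectors; the correlation
#'   is computed on the gene intersection.
#' @return Pearson r.
#' @export
cross_dataset_correlation <- function(mean_logcpm_a, mean_logcpm_b) {
  shared <- intersect(names(mean_logcpm_a), names(mean_logcpm_b))
  if (length(shared) == 0) stop("no shared genes between datasets")
  a <- mean_logcpm_a[shared]; b <- mean_logcpm_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: constant logCPM vector")
  stats::cor(a, b)
}

#' Simple per-gene differential-expression test
#'
#' Welch two-sample t-test on logCPM per gene, BH adjustment within the
#' comparison, log2 fold change as the difference of group means. A gene is
#' DE iff `q <= q_max` and `|log2FC| >= lfc_min` (both inclusive).
#'
#' @param logcpm Genes x samples matrix.
#' @param groups Group label per sample.
#' @param pair Length-2 character vector `(g1, g2)`; fold change is g1 - g2.
#' @param q_max,lfc_min Call thresholds (defaults 0.01 and 2).
#' @return Tibble: `gene_id`, `log2fc`, `p_value`, `q_value`, `is_de`.
#' @export
simple_de_test <- function(logcpm, groups, pair, q_max = 0.01, lfc_min = 2) {
  stopifnot(length(pair) == 2, all(pair %in% groups))
  i1 <- which(groups == pair[1]); i2 <- which(groups == pair[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs at least 2 samples")
  lfc <- rowMeans(logcpm[, i1, drop = FALSE]) -
    rowMeans(logcpm[, i2, drop = FALSE])
  p <- apply(logcpm, 1, function(x) {
    if (stats::sd(x[i1]) == 0 && stats::sd(x[i2]) == 0)
      return(if (mean(x[i1]) == mean(x[i2])) 1 else 0)
    stats::t.test(x[i1], x[i2])$p.value
  })
  q <- bh_adjust(p)
  tibble::tibble(gene_id = rownames(logcpm), log2fc = unname(lfc),
                 p_value = unname(p), q_value = q,
                 is_de = q <= q_max & abs(lfc) >= lfc_min)
}
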