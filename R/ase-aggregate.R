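# Per-SNP allele counts -> per-gene, per-cross pooled counts and allelic
# ratios. Reference allele = the reference-line (N. vitripennis-type) allele
# at every fixed-difference site, on both references.

#' Filtering configuration for the ASE analysis
#'
#' @param min_site_depth Minimum reads at a SNP for it to be informative
#'   (inclusive; default 30).
#' @param min_snps_per_gene Minimum informative SNPs per gene in *each* cross
#'   for the gene to be testable (default 2).
#' @param alpha FDR level for discovery calls (default 0.05).
#' @return List of class `ase_filter_config`.
#' @export
ase_filter_config <- function(min_site_depth = 30L, min_snps_per_gene = 2L,
                              alpha = 0.05) {
  stopifnot(min_site_depth >= 1, min_snps_per_gene >= 1,
            alpha > 0, alpha < 1)
  structure(list(min_site_depth = as.integer(min_site_depth),
                 min_snps_per_gene = as.integer(min_snps_per_gene),
                 alpha = alpha),
            class = "ase_filter_config")
}

#' Restrict allele-count records to fixed-difference sites
#'
#' Keeps records whose (chrom, pos) is in `diffs` *and* whose ref/alt alleles
#' equal the diff alleles; records at diff positions with mismatched alleles
#' are dropped and counted separately.
#'
#' @param records Allele-count tibble ([read_ase_table()]).
#' @param diffs Fixed-difference tibble.
#' @return Filtered records; attributes `n_in`, `n_kept`, `n_pos_dropped`,
#'   `n_allele_dropped`.
#' @export
restrict_to_fixed_sites <- function(records, diffs) {
  diffs <- validate_fixed_diff(diffs)
  key_r <- paste(records$chrom, records$pos)
  key_d <- paste(diffs$chrom, diffs$pos)
  at_diff <- key_r %in% key_d
  m <- match(key_r, key_d)
  allele_ok <- at_diff & records$ref_base == diffs$ref[m] &
    records$alt_base == diffs$alt[m]
  out <- records[which(allele_ok), , drop = FALSE]
  attr(out, "n_in") <- nrow(records)
  attr(out, "n_kept") <- nrow(out)
  attr(out, "n_pos_dropped") <- sum(!at_diff)
  attr(out, "n_allele_dropped") <- sum(at_diff & !allele_ok)
  out
}

#' Keep records with total depth at or above the informative threshold
#' @inheritParams restrict_to_fixed_sites
#' @param config An [ase_filter_config()].
#' @return Filtered records; attributes `n_in`, `n_kept`.
#' @export
filter_by_depth <- function(records, config = ase_filter_config()) {
  out <- records[records$total_count >= config$min_site_depth, , drop = FALSE]
  attr(out, "n_in") <- nrow(records)
  attr(out, "n_kept") <- nrow(out)
  out
}

#' Assign SNP records to overlapping gene spans
#'
#' A record is assigned to every gene whose `[start, end]` (1-based inclusive)
#' contains its position on the same chromosome. Records in no gene are
#' discarded; records in k > 1 genes appear under all k with `ambiguous = TRUE`.
#'
#' @inheritParams restrict_to_fixed_sites
#' @param genes Gene tibble ([read_gene_annotation()]).
#' @return Records with added `gene_id` and `ambiguous` columns (one row per
#'   record x overlapping gene); attribute `n_unassigned`.
#' @export
assign_snps_to_genes <- function(records, genes) {
  if (nrow(records) == 0L || nrow(genes) == 0L) {
    out <- dplyr::mutate(records[0, ], gene_id = character(0),
                         ambiguous = logical(0))
    attr(out, "n_unassigned") <- nrow(records)
    return(out)
  }
  rec_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(rec_gr, gene_gr, ignore.strand = TRUE)
  qi <- S4Vectors_queryHits(hits)
  si <- S4Vectors_subjectHits(hits)
  out <- records[qi, , drop = FALSE]
  out$gene_id <- genes$gene_id[si]
  # a position in >1 gene is ambiguous for every gene it touches
  n_genes_per_rec <- tabulate(qi, nbins = nrow(records))
  out$ambiguous <- n_genes_per_rec[qi] > 1L
  attr(out, "n_unassigned") <- sum(n_genes_per_rec == 0L)
  out
}

# thin indirection so the IRanges accessors are importable in one place
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' Pool replicate allele counts within one gene and cross
#'
#' Counts are summed over all SNPs and all replicates of the cross;
#' `n_snps` is the number of distinct positions surviving the filters and
#' `mean_site_depth` is the mean of `total_count` over SNP x replicate
#' observations. Invariant to record and replicate order.
#'
#' @param records Assigned records for one gene.
#' @param cross `"VG"` or `"GV"`.
#' @return One-row tibble: `n_snps`, `sum_ref`, `sum_alt`, `mean_site_depth`.
#' @export
pool_replicates <- function(records, cross) {
  stopifnot(cross %in% c("VG", "GV"))
  r <- records[records$cross == cross, , drop = FALSE]
  if (nrow(r) == 0L)
    return(tibble::tibble(n_snps = 0L, sum_ref = 0L, sum_alt = 0L,
                          mean_site_depth = NA_real_))
  tibble::tibble(
    n_snps = dplyr::n_distinct(paste(r$chrom, r$pos)),
    sum_ref = sum(r$ref_count), sum_alt = sum(r$alt_count),
    mean_site_depth = mean(r$total_count))
}

#' Summarize allele-specific expression per gene and cross
#'
#' Runs the full aggregation: restrict to fixed-difference sites, apply the
#' depth filter, intersect with gene spans, and pool replicate counts within
#' each cross. `frac_vg` / `frac_gv` are the reference-line allele fractions.
#' A gene is `testable` only with at least `min_snps_per_gene` informative
#' SNPs in *both* crosses. Per-SNP direction tallies (SNPs biased toward the
#' reference-line allele, the alternate allele, or tied, after pooling
#' replicates within cross) are emitted as diagnostics.
#'
#' @param records Allele-count records for all hybrid replicates, with a
#'   `cross` column.
#' @param genes Gene tibble.
#' @param diffs Fixed-difference tibble.
#' @param config An [ase_filter_config()].
#' @return Tibble, one row per gene with any assigned record: pooled counts,
#'   fractions, depths, SNP tallies, `ambiguous`, `testable`. Attribute
#'   `filter_log` records in/out counts for each filter.
#' @export
summarize_gene_ase <- function(records, genes, diffs,
                               config = ase_filter_config()) {
  stopifnot(all(records$cross %in% c("VG", "GV")))
  r1 <- restrict_to_fixed_sites(records, diffs)
  r2 <- filter_by_depth(r1, config)
  r3 <- assign_snps_to_genes(r2, genes)
  log <- list(
    restrict = c(n_in = attr(r1, "n_in"), n_kept = attr(r1, "n_kept"),
                 n_pos_dropped = attr(r1, "n_pos_dropped"),
                 n_allele_dropped = attr(r1, "n_allele_dropped")),
    depth = c(n_in = attr(r2, "n_in"), n_kept = attr(r2, "n_kept")),
    assign = c(n_in = nrow(r2), n_assigned = nrow(r3),
               n_unassigned = attr(r3, "n_unassigned")))
  if (nrow(r3) == 0L) {
    out <- empty_gene_summary()
    attr(out, "filter_log") <- log
    return(out)
  }
  per_snp <- dplyr::summarise(
    dplyr::group_by(r3, .data$gene_id, .data$cross, .data$chrom, .data$pos),
    ref = sum(.data$ref_count), alt = sum(.data$alt_count),
    depth_obs = list(.data$total_count), ambiguous = any(.data$ambiguous),
    .groups = "drop")
  per_gene <- dplyr::summarise(
    dplyr::group_by(per_snp, .data$gene_id, .data$cross),
    n_snps = dplyr::n(),
    sum_ref = sum(.data$ref), sum_alt = sum(.data$alt),
    mean_site_depth = mean(unlist(.data$depth_obs)),
    n_snp_ref_biased = sum(.data$ref > .data$alt),
    n_snp_alt_biased = sum(.data$alt > .data$ref),
    n_snp_no_bias = sum(.data$ref == .data$alt),
    ambiguous = any(.data$ambiguous),
    .groups = "drop")
  wide <- tidyr::pivot_wider(
    per_gene, id_cols = "gene_id", names_from = "cross",
    values_from = c("n_snps", "sum_ref", "sum_alt", "mean_site_depth",
                    "n_snp_ref_biased", "n_snp_alt_biased", "n_snp_no_bias",
                    "ambiguous"),
    names_glue = "{.value}_{tolower(cross)}")
  for (col in setdiff(summary_count_cols(), names(wide))) wide[[col]] <- 0L
  for (col in setdiff(summary_real_cols(), names(wide)))
    wide[[col]] <- NA_real_
  for (col in c("ambiguous_vg", "ambiguous_gv"))
    if (!col %in% names(wide)) wide[[col]] <- FALSE
  wide <- dplyr::mutate(
    wide,
    dplyr::across(dplyr::all_of(summary_count_cols()),
                  ~ tidyr::replace_na(as.integer(.x), 0L)),
    frac_vg = ifelse(.data$sum_ref_vg + .data$sum_alt_vg > 0,
                     .data$sum_ref_vg / (.data$sum_ref_vg + .data$sum_alt_vg),
                     NA_real_),
    frac_gv = ifelse(.data$sum_ref_gv + .data$sum_alt_gv > 0,
                     .data$sum_ref_gv / (.data$sum_ref_gv + .data$sum_alt_gv),
                     NA_real_),
    ambiguous = tidyr::replace_na(.data$ambiguous_vg, FALSE) |
      tidyr::replace_na(.data$ambiguous_gv, FALSE),
    testable = .data$n_snps_vg >= config$min_snps_per_gene &
      .data$n_snps_gv >= config$min_snps_per_gene)
  out <- dplyr::arrange(
    wide[, c("gene_id", "n_snps_vg", "n_snps_gv", "sum_ref_vg", "sum_alt_vg",
             "sum_ref_gv", "sum_alt_gv", "frac_vg", "frac_gv",
             "mean_site_depth_vg", "mean_site_depth_gv",
             "n_snp_ref_biased_vg", "n_snp_alt_biased_vg", "n_snp_no_bias_vg",
             "n_snp_ref_biased_gv", "n_snp_alt_biased_gv", "n_snp_no_bias_gv",
             "ambiguous", "testable")],
    .data$gene_id)
  attr(out, "filter_log") <- log
  out
}

summary_count_cols <- function() {
  c("n_snps_vg", "n_snps_gv", "sum_ref_vg", "sum_alt_vg", "sum_ref_gv",
    "sum_alt_gv", "n_snp_ref_biased_vg", "n_snp_alt_biased_vg",
    "n_snp_no_bias_vg", "n_snp_ref_biased_gv", "n_snp_alt_biased_gv",
    "n_snp_no_bias_gv")
}
summary_real_cols <- function() c("mean_site_depth_vg", "mean_site_depth_gv")

empty_gene_summary <- function() {
  out <- tibble::tibble(gene_id = character(0))
  for (col in summary_count_cols()) out[[col]] <- integer(0)
  out$frac_vg <- numeric(0); out$frac_gv <- numeric(0)
  out$mean_site_depth_vg <- numeric(0); out$mean_site_depth_gv <- numeric(0)
  out$ambiguous <- logical(0); out$testable <- logical(0)
  out[, c("gene_id", "n_snps_vg", "n_snps_gv", "sum_ref_vg", "sum_alt_vg",
          "sum_ref_gv", "sum_alt_gv", "frac_vg", "frac_gv",
          "mean_site_depth_vg", "mean_site_depth_gv",
          "n_snp_ref_biased_vg", "n_snp_alt_biased_vg", "n_snp_no_bias_vg",
          "n_snp_ref_biased_gv", "n_snp_alt_biased_gv", "n_snp_no_bias_gv",
          "ambiguous", "testable")]
}
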