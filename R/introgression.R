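# Introgression scanning from genotyping-array marker calls, marker-bounded
# locus construction, and gene-set/locus overlap with hypergeometric
# enrichment.

#' Build a marker-genotype panel object
#'
#' @param markers Tibble with `marker_id`, `chrom`, `pos_bp`.
#' @param calls Character matrix (markers x samples) with entries `"V"`,
#'   `"G"` or `NA`; rownames are marker ids, colnames sample ids.
#' @param roles Named character vector sample -> role in
#'   `{test, control_V, control_G}`.
#' @return List of class `marker_panel`.
#' @export
marker_panel <- function(markers, calls, roles) {
  stopifnot(all(c("marker_id", "chrom", "pos_bp") %in% names(markers)),
            identical(rownames(calls), markers$marker_id),
            all(colnames(calls) %in% names(roles)))
  stopifnot(all(roles %in% c("test", "control_V", "control_G")))
  ok <- calls %in% c("V", "G") | is.na(calls)
  if (!all(ok)) stop("marker calls must be V, G or missing")
  structure(list(markers = tibble::as_tibble(markers), calls = calls,
                 roles = roles[colnames(calls)]),
            class = "marker_panel")
}

#' Scan a marker panel for retained (non-introgressed) blocks
#'
#' A marker is *usable* iff every control sample of the reference line calls
#' `V`, every control of the other line calls `G`, and no control is missing.
#' A usable marker is *flagged* iff every test sample calls `V` with none
#' missing (missing or discordant test calls disqualify it - conservative).
#' Each maximal run of adjacent flagged markers (in usable-marker order)
#' becomes one locus spanning the interval strictly between the nearest
#' usable non-flagged markers on each side; where no such marker exists the
#' locus extends to the chromosome end (from `chrom_lengths` when supplied,
#' otherwise to the outermost marker position on that chromosome).
#'
#' @param panel A [marker_panel()].
#' @param chrom_lengths Optional named vector of chromosome lengths (bp).
#' @return List: `loci` tibble (`label`, `chrom`, `start`, `end`, `n_markers`,
#'   `marker_ids`), `flagged` (marker ids), `n_usable`, `n_markers`.
#' @export
scan_introgression <- function(panel, chrom_lengths = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  roles <- panel$roles
  if (!any(roles == "test") || !any(roles == "control_V") ||
      !any(roles == "control_G"))
    stop("panel needs test samples and both control roles")
  cv <- panel$calls[, roles == "control_V", drop = FALSE]
  cg <- panel$calls[, roles == "control_G", drop = FALSE]
  ts <- panel$calls[, roles == "test", drop = FALSE]
  usable <- rowSums(cv == "V", na.rm = TRUE) == ncol(cv) &
    rowSums(is.na(cv)) == 0 &
    rowSums(cg == "G", na.rm = TRUE) == ncol(cg) &
    rowSums(is.na(cg)) == 0
  flagged <- usable & rowSums(ts == "V", na.rm = TRUE) == ncol(ts) &
    rowSums(is.na(ts)) == 0
  mk <- panel$markers
  loci <- list()
  for (chrom in unique(mk$chrom)) {
    rows <- which(mk$chrom == chrom)
    rows <- rows[order(mk$pos_bp[rows])]
    u <- rows[usable[rows]]
    if (length(u) == 0L) {
      warning("no usable markers on chromosome ", chrom, "; skipped")
      next
    }
    fl <- flagged[u]
    if (!any(fl)) next
    runs <- rle(fl)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    chrom_end <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
      as.integer(chrom_lengths[[chrom]]) else max(mk$pos_bp[rows])
    for (j in which(runs$values)) {
      idx <- u[starts[j]:ends[j]]
      left <- if (starts[j] > 1L) mk$pos_bp[u[starts[j] - 1L]] + 1L else 1L
      right <- if (ends[j] < length(u)) mk$pos_bp[u[ends[j] + 1L]] - 1L
        else chrom_end
      loci[[length(loci) + 1L]] <- tibble::tibble(
        label = sprintf("%s_locus_%d", chrom, j),
        chrom = chrom, start = as.integer(left), end = as.integer(right),
        n_markers = length(idx),
        marker_ids = paste(mk$marker_id[idx], collapse = ","))
    }
  }
  loci <- if (length(loci)) dplyr::bind_rows(loci) else
    tibble::tibble(label = character(), chrom = character(),
                   start = integer(), end = integer(), n_markers = integer(),
                   marker_ids = character())
  loci$label <- if (nrow(loci)) sprintf("locus_%02d", seq_len(nrow(loci)))
    else character(0)
  list(loci = loci, flagged = mk$marker_id[flagged],
       n_usable = sum(usable), n_markers = nrow(mk))
}

#' Genes overlapping a locus interval
#'
#' @param locus One-row tibble with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param genes Gene tibble.
#' @return Genes whose span overlaps the locus by at least 1 bp.
#' @export
genes_in_locus <- function(locus, genes) {
  stopifnot(nrow(locus) == 1L)
  genes[genes$chrom == locus$chrom & genes$start <= locus$end &
          genes$end >= locus$start, , drop = FALSE]
}

#' Overlap statistics between two gene-id sets
#' @param set_a,set_b Character vectors of gene ids.
#' @return List: `intersection`, `n_intersection`, `frac_union` (Jaccard),
#'   `frac_a`, `frac_b`.
#' @export
gene_set_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  inter <- intersect(set_a, set_b)
  uni <- union(set_a, set_b)
  list(intersection = inter, n_intersection = length(inter),
       frac_union = if (length(uni)) length(inter) / length(uni) else NA_real_,
       frac_a = if (length(set_a)) length(inter) / length(set_a) else NA_real_,
       frac_b = if (length(set_b)) length(inter) / length(set_b) else NA_real_)
}

#' Hypergeometric enrichment of hit genes within a locus
#'
#' One-sided upper-tail test of whether `hit_genes` overlap `locus_genes`
#' more than expected when drawing `|hits|` genes from `universe`.
#'
#' @param hit_genes,locus_genes Character vectors, subsets of `universe`.
#' @param universe Background gene set.
#' @return List: `overlap` (ids), `n_overlap`, `p_value`.
#' @export
locus_enrichment <- function(hit_genes, locus_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hit_genes <- unique(hit_genes); locus_genes <- unique(locus_genes)
  if (!all(hit_genes %in% universe)) stop("hit genes outside the universe")
  if (!all(locus_genes %in% universe)) stop("locus genes outside the universe")
  k <- length(intersect(hit_genes, locus_genes))
  p <- stats::phyper(k - 1, length(locus_genes),
                     length(universe) - length(locus_genes),
                     length(hit_genes), lower.tail = FALSE)
  list(overlap = intersect(hit_genes, locus_genes), n_overlap = k,
       p_value = p)
}
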