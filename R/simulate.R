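# Seeded synthetic experiments: parental VCF, reference and truth
# pseudo-reference, gene annotation, hybrid allele-count tables,
# dual-reference count matrices, and marker panels, with known ground truth
# at every stage. Counts are simulated at the allele-counter output level
# (the pipeline's actual input boundary); read-level simulation is out of
# scope. One base seed feeds fixed per-component substreams so that, e.g.,
# adding genes does not perturb the marker simulation.

#' Configuration for a synthetic reciprocal-cross experiment
#'
#' Defaults emulate the study conditions of a reciprocal *Nasonia*-style
#' cross at desk scale: fully inbred parental lines, ~20 fixed-difference
#' SNPs per gene (matching the observed mean of ~19.7 informative SNPs per
#' gene), negative-binomial site depths with mean 150 (between the two
#' hybrids' observed mean allele depths of ~150 and ~197), 3 replicates per
#' parental line and per cross, allelic effect ratio 0.8 for non-null
#' classes, and a predominantly null gene population.
#'
#' @param seed Integer base seed; all randomness flows from it.
#' @param n_chrom,chrom_length_bp Chromosome count and length.
#' @param n_genes,gene_length_bp Gene count (split evenly over chromosomes)
#'   and span.
#' @param snp_density Fixed differences per kb within genes.
#' @param parental_replicates,hybrid_replicates Replicates per parental line
#'   / per cross direction.
#' @param class_proportions Named proportions over
#'   `null, cis, paternal_imprint, maternal_imprint`; must sum to 1.
#' @param effect_ratio Allelic fraction of the favored allele for non-null
#'   classes (in (0.5, 1)).
#' @param depth_mean,depth_dispersion Negative-binomial per-SNP total-count
#'   model (mean and size).
#' @param overdispersion_rho Beta-binomial intra-gene correlation; 0 gives
#'   binomial counts.
#' @param genotype_error_rate Probability a parental call at a fixed site is
#'   corrupted to heterozygous (the realistic failure mode for the
#'   fixed-difference filter).
#' @param n_noise_sites Non-fixed variant sites added to the parental VCF
#'   (heterozygous, polymorphic, missing, indel and multi-allelic records).
#' @param biology_seed Seed for the "biology" of the simulated organism
#'   (per-gene baseline expression and between-line expression divergence).
#'   Kept separate from `seed` so that two experiments simulated with
#'   different seeds emulate two laboratories assaying the *same* organism:
#'   they share gene-level biology and differ in sampling noise. Change it to
#'   simulate a different organism.
#' @param n_markers_per_chrom Genotyping-array markers per chromosome.
#' @param marker_blocks Tibble (`chrom`, `start`, `end`) of planted
#'   non-introgressed blocks (test samples call V inside).
#' @param marker_missing_rate Missingness among test-sample marker calls.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length_bp = 200000L,
                       n_genes = 100L, gene_length_bp = 2000L,
                       snp_density = 10,
                       parental_replicates = 3L, hybrid_replicates = 3L,
                       class_proportions = c(null = 0.94, cis = 0.03,
                                             paternal_imprint = 0.015,
                                             maternal_imprint = 0.015),
                       effect_ratio = 0.8,
                       depth_mean = 150, depth_dispersion = 5,
                       overdispersion_rho = 0,
                       genotype_error_rate = 0,
                       n_noise_sites = 50L,
                       biology_seed = 42L,
                       n_markers_per_chrom = 30L,
                       marker_blocks = NULL,
                       marker_missing_rate = 0) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            all(names(class_proportions) ==
                  c("null", "cis", "paternal_imprint", "maternal_imprint")),
            effect_ratio > 0.5, effect_ratio < 1,
            overdispersion_rho >= 0, overdispersion_rho < 1,
            depth_mean > 0, depth_dispersion > 0,
            genotype_error_rate >= 0, genotype_error_rate < 1,
            parental_replicates >= 1, hybrid_replicates >= 1,
            n_chrom >= 1, n_genes >= 1, gene_length_bp >= 100)
  structure(as.list(environment()), class = "sim_config")
}

# substream seeding: fixed offsets keep components independent of each other
sim_seed <- function(config, component) {
  offs <- c(genome = 101L, genes = 202L, vcf = 303L, ase = 404L,
            expr = 505L, markers = 606L)
  set.seed((config$seed + offs[[component]]) %% .Machine$integer.max)
}

#' Draw reference/alternate counts for one SNP
#'
#' Binomial when `rho = 0`; beta-binomial with mean `gene_fraction` and
#' intra-gene correlation `rho` otherwise.
#'
#' @param total_depth Total reads (>= 0).
#' @param gene_fraction Reference-line allele fraction in (0, 1).
#' @param rho Overdispersion in [0, 1).
#' @return Integer vector `c(ref, alt)` summing to `total_depth`.
#' @export
draw_site_counts <- function(total_depth, gene_fraction, rho = 0) {
  stopifnot(total_depth >= 0, gene_fraction > 0, gene_fraction < 1,
            rho >= 0, rho < 1)
  if (total_depth == 0) return(c(ref = 0L, alt = 0L))
  p <- if (rho == 0) gene_fraction else {
    shape <- (1 - rho) / rho
    stats::rbeta(1, gene_fraction * shape, (1 - gene_fraction) * shape)
  }
  ref <- stats::rbinom(1, total_depth, p)
  c(ref = as.integer(ref), alt = as.integer(total_depth - ref))
}

simulate_genome <- function(config) {
  sim_seed(config, "genome")
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  out <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length_bp,
                 replace = TRUE), collapse = ""), character(1))
  stats::setNames(out, chroms)
}

# gene placement, per-gene class assignment, and fixed-difference SNPs
simulate_genes <- function(config, genome) {
  sim_seed(config, "genes")
  per_chrom <- ceiling(config$n_genes / config$n_chrom)
  chroms <- names(genome)
  margin <- 200L
  spacing <- (config$chrom_length_bp - 2 * margin) / per_chrom
  if (spacing < config$gene_length_bp + 10)
    stop("infeasible config: genes exceed chromosome length")
  rows <- list()
  gi <- 0L
  for (ch in chroms) {
    for (k in seq_len(per_chrom)) {
      if (gi >= config$n_genes) break
      gi <- gi + 1L
      start <- as.integer(margin + floor((k - 1) * spacing)) + 1L
      rows[[gi]] <- tibble::tibble(
        gene_id = sprintf("gene%04d", gi), chrom = ch, start = start,
        end = start + config$gene_length_bp - 1L,
        strand = sample(c("+", "-"), 1))
    }
  }
  genes <- dplyr::bind_rows(rows)
  genes$exonic_length <- genes$end - genes$start + 1L

  cls <- sample(names(config$class_proportions), nrow(genes), replace = TRUE,
                prob = config$class_proportions)
  e <- config$effect_ratio
  # cis genes favor one line's allele in BOTH crosses but with different
  # magnitude (a between-cross difference on the same side of 0.5, the
  # pattern a cis-regulatory effect shows in this design); the weaker cross
  # sits halfway between 0.5 and the effect ratio. Direction and which cross
  # carries the stronger ratio are split evenly.
  e_lo <- 0.5 + (e - 0.5) / 2
  cis_dir <- sample(c("ref", "alt"), nrow(genes), replace = TRUE)
  cis_strong_vg <- sample(c(TRUE, FALSE), nrow(genes), replace = TRUE)
  cis_vg <- ifelse(cis_strong_vg, e, e_lo)
  cis_gv <- ifelse(cis_strong_vg, e_lo, e)
  f_vg <- ifelse(cls == "null", 0.5,
          ifelse(cls == "paternal_imprint", 1 - e,
          ifelse(cls == "maternal_imprint", e,
                 ifelse(cis_dir == "ref", cis_vg, 1 - cis_vg))))
  f_gv <- ifelse(cls == "null", 0.5,
          ifelse(cls == "paternal_imprint", e,
          ifelse(cls == "maternal_imprint", 1 - e,
                 ifelse(cis_dir == "ref", cis_gv, 1 - cis_gv))))
  n_snp <- max(2L, round(config$gene_length_bp / 1000 * config$snp_density))
  snps <- lapply(seq_len(nrow(genes)), function(i) {
    pos <- sort(sample(genes$start[i]:genes$end[i], n_snp))
    ref <- substring(genome[[genes$chrom[i]]], pos, pos)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    tibble::tibble(chrom = genes$chrom[i], pos = pos, ref = unname(ref),
                   alt = unname(alt), gene_id = genes$gene_id[i])
  })
  snps <- dplyr::bind_rows(snps)
  snps <- snps[!duplicated(snps[, c("chrom", "pos")]), ]
  truth_genes <- tibble::tibble(gene_id = genes$gene_id, class = cls,
                                f_vg = f_vg, f_gv = f_gv)
  list(genes = genes, snps = snps, truth_genes = truth_genes)
}

simulate_parental_vcf <- function(config, genome, snps) {
  sim_seed(config, "vcf")
  nv <- config$parental_replicates
  samples <- c(sprintf("VV%d", seq_len(nv)), sprintf("GG%d", seq_len(nv)))
  gt_fixed <- matrix(rep(c(rep("0/0", nv), rep("1/1", nv)),
                         each = nrow(snps)),
                     nrow = nrow(snps), dimnames = list(NULL, samples))
  if (config$genotype_error_rate > 0) {
    err <- matrix(stats::runif(length(gt_fixed)) < config$genotype_error_rate,
                  nrow = nrow(gt_fixed))
    gt_fixed[err] <- "0/1"
  }
  sites <- tibble::tibble(chrom = snps$chrom, pos = snps$pos, ref = snps$ref,
                          alt = snps$alt, n_alt = 1L)
  sites$gt <- gt_fixed

  # noise sites that must NOT pass the fixed-difference rule
  if (config$n_noise_sites > 0) {
    n <- config$n_noise_sites
    chrom <- sample(names(genome), n, replace = TRUE)
    pos <- vapply(chrom, function(ch)
      sample.int(nchar(genome[[ch]]), 1), integer(1))
    key <- paste(chrom, pos)
    keep <- !key %in% paste(snps$chrom, snps$pos) & !duplicated(key)
    chrom <- chrom[keep]; pos <- pos[keep]; n <- length(pos)
    ref <- substring(genome[chrom], pos, pos)
    alt1 <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    kind <- sample(c("het_gg", "polymorphic", "missing", "indel", "multi"),
                   n, replace = TRUE)
    alt <- ifelse(kind == "indel", paste0(alt1, "A"),
                  ifelse(kind == "multi",
                         paste0(alt1, ",",
                                vapply(seq_len(n), function(i)
                                  sample(setdiff(c("A", "C", "G", "T"),
                                                 c(ref[i], alt1[i])), 1),
                                  character(1))),
                         alt1))
    gt_noise <- matrix("0/0", nrow = n, ncol = length(samples),
                       dimnames = list(NULL, samples))
    gg_cols <- grep("^GG", samples)
    for (i in seq_len(n)) {
      gt_noise[i, gg_cols] <- switch(kind[i],
        het_gg = "0/1",
        polymorphic = sample(c("0/0", "1/1"), length(gg_cols), replace = TRUE),
        missing = { g <- rep("1/1", length(gg_cols)); g[1] <- NA; g },
        indel = "1/1",
        multi = "2/2")
    }
    noise <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                            ref = unname(ref), alt = unname(alt),
                            n_alt = ifelse(kind == "multi", 2L, 1L))
    noise$gt <- gt_noise
    sites <- dplyr::bind_rows(sites, noise)
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, ]
  colnames(sites$gt) <- samples  # bind_rows drops matrix-column dimnames
  attr(sites, "samples") <- samples
  sites
}

# hybrid allele-count records for both crosses and all replicates
simulate_hybrid_ase <- function(config, snps, truth_genes) {
  sim_seed(config, "ase")
  f <- list(VG = stats::setNames(truth_genes$f_vg, truth_genes$gene_id),
            GV = stats::setNames(truth_genes$f_gv, truth_genes$gene_id))
  rows <- list()
  for (cross in c("VG", "GV")) {
    for (rep_i in seq_len(config$hybrid_replicates)) {
      depth <- stats::rnbinom(nrow(snps), mu = config$depth_mean,
                              size = config$depth_dispersion)
      frac <- f[[cross]][snps$gene_id]
      rho <- config$overdispersion_rho
      if (rho == 0) {
        ref <- stats::rbinom(nrow(snps), depth, frac)
      } else {
        shape <- (1 - rho) / rho
        p <- stats::rbeta(nrow(snps), frac * shape, (1 - frac) * shape)
        ref <- stats::rbinom(nrow(snps), depth, p)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_rep%d", cross, rep_i), cross = cross,
        dataset = "sim", chrom = snps$chrom, pos = snps$pos,
        ref_base = snps$ref, alt_base = snps$alt,
        ref_count = as.integer(ref),
        alt_count = as.integer(depth - ref),
        total_count = as.integer(depth))
    }
  }
  dplyr::bind_rows(rows)
}

simulate_expression_counts <- function(config, genes, de_fraction = 0.1,
                                       de_log2fc = 4, species_lfc_sd = 0.7,
                                       nb_size = 20) {
  np <- config$parental_replicates; nh <- config$hybrid_replicates
  samples <- c(sprintf("VV_rep%d", seq_len(np)),
               sprintf("GG_rep%d", seq_len(np)),
               sprintf("VG_rep%d", seq_len(nh)),
               sprintf("GV_rep%d", seq_len(nh)))
  groups <- c(rep("VV", np), rep("GG", np), rep("VG", nh), rep("GV", nh))
  n <- nrow(genes)
  # biology stream: baseline expression, transcriptome-wide between-line
  # divergence, and a strongly differentially expressed subset; shared
  # between experiments that differ only in `seed`
  set.seed(config$biology_seed %% .Machine$integer.max)
  base_mu <- 2^stats::rnorm(n, mean = 7, sd = 1.5)
  lfc <- stats::rnorm(n, 0, species_lfc_sd)
  strong <- stats::runif(n) < de_fraction
  lfc[strong] <- lfc[strong] +
    sample(c(-1, 1), sum(strong), replace = TRUE) * de_log2fc
  sim_seed(config, "expr")
  # GG shifted by the per-gene divergence, hybrids intermediate
  mu <- outer(base_mu, rep(1, length(samples)))
  mu[, groups == "GG"] <- mu[, groups == "GG"] * 2^lfc
  mu[, groups %in% c("VG", "GV")] <- mu[, groups %in% c("VG", "GV")] *
    2^(lfc / 2)
  draw <- function() {
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size), nrow = n,
                dimnames = list(genes$gene_id, samples))
    storage.mode(m) <- "double"
    m
  }
  list(counts_ref = draw(), counts_pseudo = draw(), groups = groups,
       truth_de = tibble::tibble(gene_id = genes$gene_id,
                                 is_de = abs(lfc) >= 2, log2fc = lfc))
}

#' Plant non-introgressed marker blocks into a genotyping panel
#'
#' Control samples carry their own line's allele at every marker; test
#' samples carry `V` inside the planted blocks and `G` elsewhere, with
#' configurable missingness among test calls. Overlapping blocks are merged
#' with a warning.
#'
#' @param config A [sim_config()]; uses `n_markers_per_chrom`,
#'   `marker_blocks`, `marker_missing_rate`, chromosome geometry, and the
#'   marker substream of `seed`.
#' @param n_test,n_control Test / per-line control sample counts.
#' @return List: `panel` (a [marker_panel()]), `truth` tibble of per-marker
#'   planted calls, `blocks` (merged planted block intervals).
#' @export
plant_marker_blocks <- function(config, n_test = 2L, n_control = 2L) {
  sim_seed(config, "markers")
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  markers <- dplyr::bind_rows(lapply(chroms, function(ch) {
    pos <- round(seq(1000, config$chrom_length_bp - 1000,
                     length.out = config$n_markers_per_chrom))
    tibble::tibble(marker_id = sprintf("%s_m%02d", ch,
                                       seq_len(config$n_markers_per_chrom)),
                   chrom = ch, pos_bp = as.integer(pos))
  }))
  blocks <- config$marker_blocks
  if (!is.null(blocks) && nrow(blocks) > 0) {
    if (any(blocks$end < blocks$start)) stop("block end < start")
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      blocks$chrom, IRanges::IRanges(blocks$start, blocks$end)))
    merged <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                             start = GenomicRanges::start(gr),
                             end = GenomicRanges::end(gr))
    if (nrow(merged) < nrow(blocks)) warning("overlapping blocks merged")
    blocks <- merged
  } else {
    blocks <- tibble::tibble(chrom = character(), start = integer(),
                             end = integer())
  }
  in_block <- rep(FALSE, nrow(markers))
  for (i in seq_len(nrow(blocks))) {
    in_block <- in_block | (markers$chrom == blocks$chrom[i] &
                              markers$pos_bp >= blocks$start[i] &
                              markers$pos_bp <= blocks$end[i])
  }
  samples <- c(sprintf("test%d", seq_len(n_test)),
               sprintf("ctlV%d", seq_len(n_control)),
               sprintf("ctlG%d", seq_len(n_control)))
  roles <- stats::setNames(c(rep("test", n_test),
                             rep("control_V", n_control),
                             rep("control_G", n_control)), samples)
  calls <- matrix(NA_character_, nrow = nrow(markers), ncol = length(samples),
                  dimnames = list(markers$marker_id, samples))
  calls[, roles == "control_V"] <- "V"
  calls[, roles == "control_G"] <- "G"
  test_call <- ifelse(in_block, "V", "G")
  for (s in names(roles)[roles == "test"]) {
    col <- test_call
    if (config$marker_missing_rate > 0) {
      col[stats::runif(length(col)) < config$marker_missing_rate] <- NA
    }
    calls[, s] <- col
  }
  list(panel = marker_panel(markers, calls, roles),
       truth = tibble::tibble(marker_id = markers$marker_id,
                              planted_call = test_call),
       blocks = blocks)
}

#' Simulate a complete experiment bundle
#'
#' Emits every input the pipeline consumes - reference FASTA, parental
#' multi-sample VCF, GFF3 gene annotation, per-replicate hybrid allele-count
#' TSVs, dual-reference gene count TSVs, a marker CSV with sample roles, and
#' a sample design table - together with the ground truth for every stage.
#' Identical seeds produce byte-identical bundles.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created); when `NULL` nothing is written
#'   and the in-memory objects alone are returned.
#' @return List with `genome`, `genes`, `snps` (the true fixed-difference
#'   set with `gene_id`), `sites` (parental VCF table), `records` (hybrid
#'   allele counts), `expr` (count matrices + DE truth), `markers`
#'   (panel + truth), `truth_genes`, and `paths` (when written).
#' @export
simulate_experiment <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome(config)
  gs <- simulate_genes(config, genome)
  sites <- simulate_parental_vcf(config, genome, gs$snps)
  records <- simulate_hybrid_ase(config, gs$snps, gs$truth_genes)
  expr <- simulate_expression_counts(config, gs$genes)
  markers <- plant_marker_blocks(config)
  out <- list(genome = genome, genes = gs$genes, snps = gs$snps,
              sites = sites, records = records, expr = expr,
              markers = markers, truth_genes = gs$truth_genes,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      fasta = file.path(out_dir, "reference.fa"),
      vcf = file.path(out_dir, "parents.vcf"),
      gff3 = file.path(out_dir, "genes.gff3"),
      counts_ref = file.path(out_dir, "counts_ref.tsv"),
      counts_pseudo = file.path(out_dir, "counts_pseudo.tsv"),
      markers = file.path(out_dir, "markers.csv"),
      roles = file.path(out_dir, "marker_roles.tsv"),
      design = file.path(out_dir, "samples.tsv"))
    write_fasta(genome, p$fasta)
    write_vcf(sites, p$vcf)
    write_gff3(gs$genes, p$gff3)
    write_counts_matrix(expr$counts_ref, p$counts_ref)
    write_counts_matrix(expr$counts_pseudo, p$counts_pseudo)
    design <- dplyr::distinct(records[, c("sample_id", "cross")])
    design$path <- paste0("ase_", design$sample_id, ".tsv")  # bundle-relative
    for (i in seq_len(nrow(design))) {
      write_ase_table(records[records$sample_id == design$sample_id[i], ],
                      file.path(out_dir, design$path[i]))
    }
    utils::write.table(as.data.frame(design), p$design, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mk <- markers$panel
    utils::write.csv(cbind(as.data.frame(mk$markers),
                           as.data.frame(mk$calls, check.names = FALSE)),
                     p$markers, row.names = FALSE)
    utils::write.table(data.frame(sample_id = names(mk$roles),
                                  role = unname(mk$roles)),
                       p$roles, sep = "\t", quote = FALSE, row.names = FALSE)
    p$ase <- file.path(out_dir, design$path)
    out$paths <- p
  }
  out
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(c(
      paste(g$chrom, "sim", "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "sim", "exon", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id, ".e1;Parent=", g$gene_id), sep = "\t")),
      con)
  }
  invisible(path)
}

write_counts_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
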