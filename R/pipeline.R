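# End-to-end orchestration over a bundle directory (as produced by
# simulate_experiment): fixed-difference calling, pseudo-reference
# construction and verification, ASE aggregation, the imprinting test, and
# the expression-QC stage, with a machine-readable run report.

#' Pipeline configuration
#'
#' @param bundle_dir Directory holding `reference.fa`, `parents.vcf`,
#'   `genes.gff3`, `samples.tsv` (columns `sample_id`, `cross`, `path`),
#'   `counts_ref.tsv`, `counts_pseudo.tsv`.
#' @param group_a,group_b Parental sample IDs carrying the reference /
#'   alternate alleles (default: all samples named `VV*` / `GG*` in the VCF).
#' @param ase Filtering configuration ([ase_filter_config()]).
#' @param calls Call configuration ([imprint_call_config()]).
#' @param de_q_max,de_lfc_min DE thresholds (defaults 0.01 and 2).
#' @param out_dir Where result tables are written; `NULL` keeps results
#'   in memory only.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dir, group_a = NULL, group_b = NULL,
                            ase = ase_filter_config(),
                            calls = imprint_call_config(),
                            de_q_max = 0.01, de_lfc_min = 2,
                            out_dir = NULL) {
  required <- c("reference.fa", "parents.vcf", "genes.gff3", "samples.tsv",
                "counts_ref.tsv", "counts_pseudo.tsv")
  missing <- required[!file.exists(file.path(bundle_dir, required))]
  if (length(missing))
    stop("missing input file(s) in bundle: ", paste(missing, collapse = ", "))
  structure(list(bundle_dir = bundle_dir, group_a = group_a,
                 group_b = group_b, ase = ase, calls = calls,
                 de_q_max = de_q_max, de_lfc_min = de_lfc_min,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a bundle
#'
#' Stages run in dependency order; the returned report records, per stage,
#' the record counts in/out of every filter and md5 hashes of input and
#' written output files. The pipeline itself draws no random numbers, so a
#' given bundle always yields identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List: `fixed_diffs`, `pseudo_check`, `gene_summaries`,
#'   `imprinting`, `expr` (logCPM, PCA, DE table), `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  bd <- config$bundle_dir
  report <- list(inputs = file_hashes(bd))

  sites <- read_vcf(file.path(bd, "parents.vcf"))
  samples <- attr(sites, "samples")
  group_a <- config$group_a %||% grep("^VV", samples, value = TRUE)
  group_b <- config$group_b %||% grep("^GG", samples, value = TRUE)
  diffs <- build_fixed_difference_set(sites, group_a, group_b)
  report$fixed_diff <- c(n_sites_in = nrow(sites), n_fixed = nrow(diffs),
                         n_not_biallelic = attr(diffs, "n_not_biallelic"))

  genome <- read_fasta(file.path(bd, "reference.fa"))
  pseudo <- build_pseudo_reference(genome, diffs)
  check <- verify_pseudo_reference(genome, pseudo, diffs)
  if (!check$clean) stop("pseudo-reference verification failed")
  report$pseudo_ref <- c(n_substitutions = nrow(diffs), clean = 1)

  genes <- read_gene_annotation(file.path(bd, "genes.gff3"), "gff3")
  design <- utils::read.delim(file.path(bd, "samples.tsv"),
                              stringsAsFactors = FALSE)
  # design paths are bundle-relative unless already absolute
  design$path <- ifelse(file.exists(design$path), design$path,
                        file.path(bd, design$path))
  records <- dplyr::bind_rows(lapply(seq_len(nrow(design)), function(i)
    read_ase_table(design$path[i], sample_id = design$sample_id[i],
                   cross = design$cross[i], dataset = "bundle")))
  summaries <- summarize_gene_ase(records, genes, diffs, config$ase)
  report$ase <- attr(summaries, "filter_log")
  report$ase$genes <- c(n_genes = nrow(summaries),
                        n_testable = sum(summaries$testable))
  imprinting <- run_imprinting_analysis(summaries, config$calls)
  sig <- imprinting$category %in% c("paternal_bias", "maternal_bias")
  report$imprinting <- c(
    n_testable = sum(imprinting$testable),
    n_significant = sum(!is.na(imprinting$q_value) &
                          imprinting$q_value <= config$calls$alpha),
    n_imprinted = sum(sig))

  counts_ref <- read_counts_matrix(file.path(bd, "counts_ref.tsv"))
  counts_pseudo <- read_counts_matrix(file.path(bd, "counts_pseudo.tsv"))
  avg <- average_dual_counts(counts_ref, counts_pseudo)
  groups <- sub("_rep[0-9]+$", "", colnames(avg))
  lengths <- stats::setNames(genes$exonic_length, genes$gene_id)
  filtered <- filter_low_expression(avg, lengths, groups)
  lcpm <- log_cpm(filtered)
  pca <- pca_summary(lcpm)
  de <- simple_de_test(lcpm, groups, c("VV", "GG"),
                       q_max = config$de_q_max, lfc_min = config$de_lfc_min)
  report$expr <- c(n_genes_in = nrow(avg), n_genes_kept = nrow(filtered),
                   n_de = sum(de$is_de),
                   pc1_prop = round(pca$proportions[1], 4))

  out <- list(fixed_diffs = diffs, pseudo_check = check,
              gene_summaries = summaries, imprinting = imprinting,
              expr = list(logcpm = lcpm, pca = pca, de = de),
              report = report)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fixed_diff(diffs, file.path(config$out_dir, "fixed_diffs.tsv"))
    utils::write.table(as.data.frame(imprinting),
                       file.path(config$out_dir, "imprint_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(de),
                       file.path(config$out_dir, "de_vv_gg.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # scatter-ready export of the two reference-line allele fractions
    utils::write.table(
      as.data.frame(imprinting[imprinting$testable,
                               c("gene_id", "frac_vg", "frac_gv")]),
      file.path(config$out_dir, "ase_fractions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    out$report$outputs <- file_hashes(config$out_dir)
  }
  out
}

file_hashes <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!file.info(files)$isdir]
  h <- tools::md5sum(files)
  stats::setNames(unname(h), basename(files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
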