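# Shared fixture builders. Everything is generated in code; no stored data.

# a site table in the shape read_vcf() returns
make_sites <- function(chrom, pos, ref, alt, gt_rows, samples) {
  gt <- do.call(rbind, gt_rows)
  colnames(gt) <- samples
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                        alt = alt,
                        n_alt = lengths(strsplit(alt, ",", fixed = TRUE)))
  out$gt <- gt
  attr(out, "samples") <- samples
  out
}

# allele-count records for one or more SNPs of one sample
make_records <- function(chrom, pos, ref_base, alt_base, ref_count, alt_count,
                         sample_id = "s1", cross = "VG", dataset = "d") {
  tibble::tibble(sample_id = sample_id, cross = cross, dataset = dataset,
                 chrom = chrom, pos = as.integer(pos),
                 ref_base = ref_base, alt_base = alt_base,
                 ref_count = as.integer(ref_count),
                 alt_count = as.integer(alt_count),
                 total_count = as.integer(ref_count + alt_count))
}

# per-gene records in both crosses: n_snps SNPs at the given per-SNP depths
# and a common reference-allele fraction, one replicate per cross
make_gene_records <- function(gene_idx, chrom, start_pos, depths_vg, frac_vg,
                              depths_gv, frac_gv) {
  n_vg <- length(depths_vg); n_gv <- length(depths_gv)
  pos <- start_pos + seq_len(max(n_vg, n_gv)) - 1L
  ref_vg <- round(depths_vg * frac_vg)
  ref_gv <- round(depths_gv * frac_gv)
  dplyr::bind_rows(
    make_records(chrom, pos[seq_len(n_vg)], "A", "G",
                 ref_vg, depths_vg - ref_vg, sample_id = "vg1", cross = "VG"),
    make_records(chrom, pos[seq_len(n_gv)], "A", "G",
                 ref_gv, depths_gv - ref_gv, sample_id = "gv1", cross = "GV"))
}

# minimal gene table
make_genes <- function(gene_id, chrom, start, end, strand = "+") {
  tibble::tibble(gene_id = gene_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, exonic_length = as.integer(end - start + 1L))
}

diffs_from_records <- function(records) {
  d <- dplyr::distinct(records[, c("chrom", "pos", "ref_base", "alt_base")])
  tibble::tibble(chrom = d$chrom, pos = d$pos, ref = d$ref_base,
                 alt = d$alt_base)
}

# a gene-summary table built directly from pooled counts (bypasses record
# aggregation) for statistical simulations
make_summaries <- function(ref_vg, alt_vg, ref_gv, alt_gv, n_snps = 5L) {
  n <- length(ref_vg)
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    n_snps_vg = n_snps, n_snps_gv = n_snps,
    sum_ref_vg = as.integer(ref_vg), sum_alt_vg = as.integer(alt_vg),
    sum_ref_gv = as.integer(ref_gv), sum_alt_gv = as.integer(alt_gv),
    frac_vg = ref_vg / (ref_vg + alt_vg),
    frac_gv = ref_gv / (ref_gv + alt_gv),
    mean_site_depth_vg = (ref_vg + alt_vg) / n_snps,
    mean_site_depth_gv = (ref_gv + alt_gv) / n_snps,
    n_snp_ref_biased_vg = 0L, n_snp_alt_biased_vg = 0L, n_snp_no_bias_vg = 0L,
    n_snp_ref_biased_gv = 0L, n_snp_alt_biased_gv = 0L, n_snp_no_bias_gv = 0L,
    ambiguous = FALSE, testable = TRUE)
}

# independent oracle for the fixed-difference rule, coded from the rule text
# without reference to the package implementation
oracle_fixed_diff <- function(ref, alt, gt_a, gt_b) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  if (length(alts) != 1) return("not_biallelic_snp")
  if (nchar(ref) != 1 || nchar(alts) != 1) return("not_biallelic_snp")
  if (!ref %in% c("A", "C", "G", "T") || !alts %in% c("A", "C", "G", "T"))
    return("not_biallelic_snp")
  if (any(is.na(gt_a)) || any(is.na(gt_b))) return("not_fixed")
  if (all(gt_a == "0/0") && all(gt_b == "1/1")) "fixed_different" else
    "not_fixed"
}

# exhaustive hypergeometric oracle for the two-sided Fisher test, using
# factorials directly (independent of dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(NA_real_)
  support <- max(0, k - n):min(k, m)
  lp <- vapply(support, function(x)
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k), numeric(1))
  probs <- exp(lp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# step-up definition applied literally: q_i = min over j with p_(j) >= p_i
# of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi - 1e-15)
    min(1, min(sp[js] * m / js))
  }, numeric(1))
}
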