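# Per-gene tests of allelic-ratio differences between reciprocal hybrids,
# FDR control, and classification into parent-of-origin vs species-of-origin
# (cis) categories.
#
# The 2x2 table per gene is
#                    cross VG   cross GV
#   ref-line allele      a          b
#   alt-line allele      c          d
# and the two-sided Fisher p is the sum of hypergeometric probabilities no
# larger than that of the observed table, at fixed margins.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computed by direct summation of hypergeometric probabilities over the
#' support defined by the table margins. Any zero margin makes the table
#' untestable and returns `NA`.
#'
#' @param a,b,c,d Non-negative counts (row 1: `a`, `b`; row 2: `c`, `d`).
#' @return Two-sided p-value in (0, 1], or `NA_real_` for a zero margin.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row-1 total
  n <- c + d          # row-2 total
  k <- a + c          # column-1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(NA_real_)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance absorbs floating noise in the <= comparison
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_i = min over j with p_(j) >= p_i of p_(j) * m / j`, clipped at 1; the
#' input order is preserved. All-equal inputs give `q = p`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

#' Exact two-sided binomial test of allelic balance within one hybrid
#'
#' Tests H0: reference-line allele fraction = 0.5 by summing binomial(n, 0.5)
#' probabilities no larger than that of the observed count. A supporting
#' diagnostic; it does not gate imprinting calls.
#'
#' @param sum_ref,sum_alt Pooled allele counts.
#' @return Two-sided exact p-value, or `NA_real_` when the total is zero.
#' @export
per_hybrid_bias_test <- function(sum_ref, sum_alt) {
  stopifnot(sum_ref >= 0, sum_alt >= 0)
  n <- sum_ref + sum_alt
  if (n == 0) return(NA_real_)
  probs <- stats::dbinom(0:n, n, 0.5)
  p_obs <- probs[sum_ref + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Call configuration for imprinting/cis classification
#' @param alpha FDR threshold for significance (default 0.05).
#' @param tie_policy What a fraction exactly at 0.5 means: `"no_direction"`
#'   (classify by the other cross's side; both at 0.5 gives `no_difference`).
#' @return List of class `imprint_call_config`.
#' @export
imprint_call_config <- function(alpha = 0.05, tie_policy = "no_direction") {
  stopifnot(alpha > 0, alpha < 1, tie_policy == "no_direction")
  structure(list(alpha = alpha, tie_policy = tie_policy),
            class = "imprint_call_config")
}

#' Classify genes by allelic-ratio geometry
#'
#' For significant genes (q <= alpha), with `f_vg`, `f_gv` the reference-line
#' allele fractions in the two crosses: fractions on opposite sides of 0.5
#' indicate a parent-of-origin effect (`paternal_bias` when the paternal
#' allele is favored in both crosses, i.e. f_vg < 0.5 < f_gv; `maternal_bias`
#' when mirrored); fractions on the same side indicate a species-of-origin
#' cis effect (`cis_ref_parent` when both favor the reference line,
#' `cis_alt_parent` otherwise). Non-significant genes are `no_difference`.
#'
#' @param f_vg,f_gv Reference-line allele fractions.
#' @param q_value BH-adjusted p-values.
#' @param config An [imprint_call_config()].
#' @param testable Logical; untestable genes get `not_testable`.
#' @return Character vector of categories.
#' @export
classify_gene <- function(f_vg, f_gv, q_value,
                          config = imprint_call_config(),
                          testable = TRUE) {
  n <- max(length(f_vg), length(f_gv), length(q_value))
  f_vg <- rep_len(f_vg, n); f_gv <- rep_len(f_gv, n)
  q_value <- rep_len(q_value, n); testable <- rep_len(testable, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (!isTRUE(testable[i]) || is.na(q_value[i])) {
      "not_testable"
    } else if (q_value[i] > config$alpha) {
      "no_difference"
    } else {
      a <- f_vg[i]; b <- f_gv[i]
      if (a == 0.5 && b == 0.5) "no_difference"
      else if (a == 0.5) if (b > 0.5) "cis_ref_parent" else "cis_alt_parent"
      else if (b == 0.5) if (a > 0.5) "cis_ref_parent" else "cis_alt_parent"
      else if (a < 0.5 && b > 0.5) "paternal_bias"
      else if (a > 0.5 && b < 0.5) "maternal_bias"
      else if (a > 0.5) "cis_ref_parent"
      else "cis_alt_parent"
    }
  }
  out
}

#' Run the imprinting analysis on per-gene summaries
#'
#' Computes the two-sided Fisher p on each testable gene's pooled 2x2 table,
#' applies Benjamini-Hochberg across the testable set only, attaches per-cross
#' exact-binomial diagnostics, and classifies each gene. Output is sorted by
#' q-value then gene id.
#'
#' @param summaries Gene summary tibble from [summarize_gene_ase()].
#' @param config An [imprint_call_config()].
#' @return `summaries` with added `p_value`, `q_value`, `p_binom_vg`,
#'   `p_binom_gv`, `category`.
#' @export
run_imprinting_analysis <- function(summaries,
                                    config = imprint_call_config()) {
  if (nrow(summaries) == 0L) {
    out <- summaries
    out$p_value <- numeric(0); out$q_value <- numeric(0)
    out$p_binom_vg <- numeric(0); out$p_binom_gv <- numeric(0)
    out$category <- character(0)
    return(out)
  }
  p <- rep(NA_real_, nrow(summaries))
  for (i in which(summaries$testable)) {
    p[i] <- fisher_exact_two_sided(summaries$sum_ref_vg[i],
                                   summaries$sum_ref_gv[i],
                                   summaries$sum_alt_vg[i],
                                   summaries$sum_alt_gv[i])
  }
  q <- rep(NA_real_, nrow(summaries))
  testable_p <- which(summaries$testable & !is.na(p))
  q[testable_p] <- bh_adjust(p[testable_p])
  out <- summaries
  out$p_value <- p
  out$q_value <- q
  out$p_binom_vg <- mapply(per_hybrid_bias_test,
                           summaries$sum_ref_vg, summaries$sum_alt_vg)
  out$p_binom_gv <- mapply(per_hybrid_bias_test,
                           summaries$sum_ref_gv, summaries$sum_alt_gv)
  out$category <- classify_gene(out$frac_vg, out$frac_gv, out$q_value,
                                config, out$testable)
  dplyr::arrange(out, !is.na(.data$q_value), .data$q_value, .data$gene_id)
}

#' Combined-dataset imprinting analysis restricted to shared sites
#'
#' Restricts both record sets to the allele-consistent intersection of the
#' two fixed-difference sets, pools counts per gene and cross across the
#' datasets, and reruns the analysis as its own BH family. Positions present
#' in both sets with disagreeing alleles are dropped and counted.
#'
#' @param records_a,records_b Allele-count records of the two datasets.
#' @param diffs_a,diffs_b Their fixed-difference sets.
#' @param genes Gene tibble (shared reference coordinates).
#' @param config An [ase_filter_config()].
#' @param call_config An [imprint_call_config()].
#' @return Result tibble as from [run_imprinting_analysis()]; attributes
#'   `n_shared_sites`, `n_allele_conflicts`.
#' @export
combine_datasets <- function(records_a, records_b, diffs_a, diffs_b, genes,
                             config = ase_filter_config(),
                             call_config = imprint_call_config()) {
  shared <- dplyr::inner_join(validate_fixed_diff(diffs_a),
                              validate_fixed_diff(diffs_b),
                              by = c("chrom", "pos"), suffix = c("", "_b"))
  agree <- shared$ref == shared$ref_b & shared$alt == shared$alt_b
  diffs <- shared[agree, c("chrom", "pos", "ref", "alt")]
  records <- dplyr::bind_rows(records_a, records_b)
  summaries <- summarize_gene_ase(records, genes, diffs, config)
  out <- run_imprinting_analysis(summaries, call_config)
  attr(out, "n_shared_sites") <- nrow(diffs)
  attr(out, "n_allele_conflicts") <- sum(!agree)
  attr(out, "filter_log") <- attr(summaries, "filter_log")
  out
}
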