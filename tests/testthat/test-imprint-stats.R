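test_that("two-sided Fisher p behaves on canonical tables", {
  expect_equal(fisher_exact_two_sided(10, 10, 10, 10), 1)
  # transposition symmetry
  set.seed(1)
  for (i in 1:20) {
    t <- sample(0:15, 4, replace = TRUE)
    if (sum(t[1:2]) == 0 || sum(t[3:4]) == 0 ||
        t[1] + t[3] == 0 || t[2] + t[4] == 0) next
    expect_equal(fisher_exact_two_sided(t[1], t[2], t[3], t[4]),
                 fisher_exact_two_sided(t[1], t[3], t[2], t[4]),
                 tolerance = 1e-12)
  }
  # zero margin is untestable
  expect_true(is.na(fisher_exact_two_sided(0, 0, 5, 5)))
  expect_true(is.na(fisher_exact_two_sided(0, 5, 0, 5)))
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(2)
  for (i in 1:50) {
    t <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact_two_sided(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 stats::fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("the per-hybrid exact binomial test matches closed forms", {
  expect_equal(per_hybrid_bias_test(10, 10), 1)
  expect_equal(per_hybrid_bias_test(30, 0), 2 * 0.5^30, tolerance = 1e-12)
  expect_true(is.na(per_hybrid_bias_test(0, 0)))
  # enumeration oracle via binom.test for totals up to 50
  set.seed(4)
  for (i in 1:40) {
    n <- sample(1:50, 1); k <- sample(0:n, 1)
    expect_equal(per_hybrid_bias_test(k, n - k),
                 stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-9)
  }
})

test_that("categories follow the corner geometry of the reciprocal design", {
  cfg <- imprint_call_config(alpha = 0.05)
  # printed worked cases: paternal bias and reference-line cis effect
  expect_equal(classify_gene(0.347, 0.62, 0.01, cfg), "paternal_bias")
  expect_equal(classify_gene(0.93, 0.61, 0.01, cfg), "cis_ref_parent")
  expect_equal(classify_gene(0.62, 0.347, 0.01, cfg), "maternal_bias")
  expect_equal(classify_gene(0.2, 0.35, 0.01, cfg), "cis_alt_parent")
  expect_equal(classify_gene(0.347, 0.62, 0.5, cfg), "no_difference")
  # ties at exactly 0.5 carry no direction
  expect_equal(classify_gene(0.5, 0.62, 0.01, cfg), "cis_ref_parent")
  expect_equal(classify_gene(0.5, 0.35, 0.01, cfg), "cis_alt_parent")
  expect_equal(classify_gene(0.5, 0.5, 0.01, cfg), "no_difference")
  expect_equal(classify_gene(0.3, 0.7, NA_real_, cfg, testable = FALSE),
               "not_testable")
})

test_that("the analysis tests only testable genes and sorts by q", {
  s <- make_summaries(ref_vg = c(100, 250, 50), alt_vg = c(400, 250, 450),
                      ref_gv = c(400, 250, 250), alt_gv = c(100, 250, 250))
  s$testable[3] <- FALSE
  res <- run_imprinting_analysis(s)
  expect_true(is.na(res$p_value[res$gene_id == "g00003"]))
  expect_equal(res$category[res$gene_id == "g00003"], "not_testable")
  expect_equal(res$category[res$gene_id == "g00001"], "paternal_bias")
  expect_equal(res$category[res$gene_id == "g00002"], "no_difference")
  # BH family is the testable set only (m = 2 here)
  p_t <- res$p_value[match(c("g00001", "g00002"), res$gene_id)]
  expect_equal(sort(res$q_value[!is.na(res$q_value)]), sort(bh_adjust(p_t)))
  expect_false(is.unsorted(res$q_value[!is.na(res$q_value)]))
  expect_equal(nrow(run_imprinting_analysis(s[0, ])), 0)
})

test_that("null genes stay quiet and planted effects are recovered", {
  set.seed(10)
  n_null <- 400; depth <- 500
  ref_vg <- rbinom(n_null, depth, 0.5); ref_gv <- rbinom(n_null, depth, 0.5)
  s_null <- make_summaries(ref_vg, depth - ref_vg, ref_gv, depth - ref_gv)
  res <- run_imprinting_analysis(s_null)
  rate <- mean(res$p_value <= 0.05)
  mc_se <- sqrt(0.05 * 0.95 / n_null)
  expect_lt(abs(rate - 0.05), 3 * mc_se)

  n_imp <- 40
  ref_vg2 <- rbinom(n_imp, depth, 0.2); ref_gv2 <- rbinom(n_imp, depth, 0.8)
  s <- make_summaries(c(ref_vg, ref_vg2), c(depth - ref_vg, depth - ref_vg2),
                      c(ref_gv, ref_gv2), c(depth - ref_gv, depth - ref_gv2))
  planted_ids <- sprintf("g%05d", n_null + seq_len(n_imp))
  res2 <- run_imprinting_analysis(s)
  hits <- res2$gene_id[res2$category == "paternal_bias"]
  expect_gt(length(intersect(hits, planted_ids)) / n_imp, 0.9)
})

test_that("sensitivity is monotone in effect size under common random numbers", {
  set.seed(12)
  n <- 300; depth <- 300
  u_vg <- runif(n); u_gv <- runif(n)
  sens <- vapply(c(0.6, 0.7, 0.8), function(e) {
    ref_vg <- qbinom(u_vg, depth, 1 - e)
    ref_gv <- qbinom(u_gv, depth, e)
    s <- make_summaries(ref_vg, depth - ref_vg, ref_gv, depth - ref_gv)
    res <- run_imprinting_analysis(s)
    mean(res$category == "paternal_bias")
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("combining datasets restricts to shared allele-consistent sites", {
  genes <- make_genes("gA", "chr1", 100, 200)
  rec_a <- make_gene_records(1, "chr1", 110, c(100, 100), 0.3,
                             c(100, 100), 0.8)
  rec_b <- rec_a
  diffs_a <- diffs_from_records(rec_a)
  # disjoint diff sets -> nothing testable
  diffs_far <- dplyr::mutate(diffs_a, pos = pos + 5000L)
  res0 <- combine_datasets(rec_a, rec_b, diffs_a, diffs_far, genes)
  expect_equal(nrow(res0), 0)
  expect_equal(attr(res0, "n_shared_sites"), 0L)

  # identical datasets pool to doubled counts
  res1 <- combine_datasets(rec_a, rec_b, diffs_a, diffs_a, genes)
  single <- run_imprinting_analysis(
    summarize_gene_ase(rec_a, genes, diffs_a))
  expect_equal(res1$sum_ref_vg, 2L * single$sum_ref_vg)
  expect_equal(res1$category, single$category)

  # allele conflict at a shared position drops the site
  diffs_conflict <- diffs_a
  diffs_conflict$alt[1] <- "C"
  res2 <- combine_datasets(rec_a, rec_b, diffs_a, diffs_conflict, genes)
  expect_equal(attr(res2, "n_allele_conflicts"), 1L)
  expect_equal(attr(res2, "n_shared_sites"), nrow(diffs_a) - 1L)
})
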