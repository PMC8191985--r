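mk_counts <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), dimnames = list(genes, samples))
}

test_that("dual-reference counts average elementwise", {
  a <- mk_counts(c(10, 0, 4, 6), c("g1", "g2"), c("s1", "s2"))
  b <- mk_counts(c(20, 2, 4, 6), c("g1", "g2"), c("s1", "s2"))
  expect_equal(average_dual_counts(a, b)["g1", "s1"], 15)
  expect_equal(average_dual_counts(a, a), a)
  # column/row order differences are aligned, not an error
  expect_equal(average_dual_counts(a, b[2:1, 2:1]), (a + b) / 2)
  expect_error(average_dual_counts(a, b[1, , drop = FALSE]),
               "gene sets differ.*g2")
})

test_that("FPKM follows its definition", {
  counts <- mk_counts(c(10, 999990, 5, 999995), c("g1", "g2"),
                      c("s1", "s2"))
  lens <- c(g1 = 1000, g2 = 10000)
  f <- fpkm(counts, lens)
  expect_equal(f["g1", "s1"], 10)  # 10 reads, 1 kb gene, 1e6 library
  expect_equal(fpkm(counts * 0 + c(0, 1), lens)["g1", ], c(s1 = 0, s2 = 0))
  # random fixture vs direct recomputation
  set.seed(5)
  m <- matrix(rpois(60, 50), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  l <- stats::setNames(sample(200:5000, 10), rownames(m))
  f2 <- fpkm(m, l)
  for (i in 1:10) for (j in 1:6)
    expect_equal(f2[i, j], m[i, j] * 1e9 / (l[[i]] * sum(m[, j])),
                 tolerance = 1e-12)
  expect_error(fpkm(m * 0, l), "zero library size")
})

test_that("low-expression filtering keeps any group mean at or above 0.5", {
  lens <- c(gBig = 1000, g1 = 1000, g2 = 1000, g3 = 1000)
  groups <- c("VV", "VV", "GG", "GG")
  counts <- rbind(
    gBig = rep(1e6, 4),            # filler fixing library size ~1e6
    g1 = c(2000, 2000, 0.2, 0.2),  # high in VV only -> kept
    g2 = c(0.2, 0.2, 0.2, 0.2),    # low everywhere -> dropped
    g3 = c(0.2, 0.2, 1, 1))
  colnames(counts) <- paste0("s", 1:4)
  out <- filter_low_expression(counts, lens, groups)
  expect_true("g1" %in% rownames(out))
  expect_false("g2" %in% rownames(out))
  # the threshold is inclusive: a group mean exactly at it keeps the gene
  g3_gg_mean <- mean(fpkm(counts, lens)["g3", 3:4])
  expect_true("g3" %in% rownames(
    filter_low_expression(counts, lens, groups, min_fpkm = g3_gg_mean)))
  expect_false("g3" %in% rownames(
    filter_low_expression(counts, lens, groups,
                          min_fpkm = g3_gg_mean * (1 + 1e-9))))
  # idempotent and a subset of the input
  expect_equal(filter_low_expression(out, lens, groups), out)
  expect_true(all(rownames(out) %in% rownames(counts)))
})

test_that("logCPM matches its formula and limiting behavior", {
  counts <- mk_counts(c(100, 999900), c("g1", "g2"), "s1")
  # prior -> 0 recovers log2 CPM of the raw proportions
  expect_equal(log_cpm(counts, prior = 1e-9)["g1", 1], log2(100),
               tolerance = 1e-6)
  set.seed(6)
  m <- matrix(rpois(40, 30), 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  lc <- log_cpm(m, prior = 0.5)
  for (j in 1:5)
    expect_equal(lc[, j],
                 log2((m[, j] + 0.5) / (sum(m[, j]) + 1) * 1e6),
                 tolerance = 1e-12)
  z <- mk_counts(c(0, 0), c("g1", "g2"), "s1")
  expect_equal(diff(log_cpm(z)[, 1]), c(g2 = 0))  # all-zero sample constant
})

test_that("PCA proportions normalize and separate planted clusters", {
  set.seed(7)
  base <- rnorm(200)
  shift <- c(rep(0, 3), rep(4, 3))
  m <- sapply(1:6, function(j) base + shift[j] * c(rep(1, 100), rep(0, 100)) +
                rnorm(200, sd = 0.3))
  rownames(m) <- paste0("g", 1:200); colnames(m) <- paste0("s", 1:6)
  p <- pca_summary(m)
  expect_equal(sum(p$proportions), 1, tolerance = 1e-12)
  expect_gt(p$proportions[1], max(p$proportions[-1]))
  pc1 <- p$projections[, 1]
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) ||
                min(pc1[1:3]) > max(pc1[4:6]))
  expect_error(pca_summary(m[, 1, drop = FALSE]), "at least 2 samples")
  # permuting samples permutes projections correspondingly
  perm <- c(3, 1, 2, 6, 4, 5)
  p2 <- pca_summary(m[, perm])
  expect_equal(abs(p2$projections[colnames(m), 1]), abs(pc1),
               tolerance = 1e-8)
})

test_that("cross-dataset correlation behaves on canonical vectors", {
  v <- stats::setNames(rnorm(50), paste0("g", 1:50))
  expect_equal(cross_dataset_correlation(v, v), 1)
  expect_equal(cross_dataset_correlation(v, -v), -1)
  w <- stats::setNames(rnorm(50), paste0("g", 26:75))
  shared <- paste0("g", 26:50)
  expect_equal(cross_dataset_correlation(v, w),
               stats::cor(v[shared], w[shared]))
  expect_error(cross_dataset_correlation(v, stats::setNames(1, "gX")),
               "no shared genes")
  expect_error(cross_dataset_correlation(v, v * 0), "constant")
})

test_that("the simple DE stage flags planted fold changes", {
  set.seed(8)
  n <- 200; reps <- 4
  groups <- rep(c("VV", "GG"), each = reps)
  base <- matrix(rnorm(n * 2 * reps, 8, 0.1), n)
  de_idx <- 1:20
  base[de_idx, groups == "GG"] <- base[de_idx, groups == "GG"] + 4
  rownames(base) <- paste0("g", 1:n)
  colnames(base) <- paste0("s", 1:(2 * reps))
  res <- simple_de_test(base, groups, c("GG", "VV"))
  expect_gt(mean(res$is_de[de_idx]), 0.9)
  expect_equal(sum(res$is_de[-de_idx]), 0)
  expect_equal(res$log2fc[1],
               mean(base[1, groups == "GG"]) - mean(base[1, groups == "VV"]))
  # identical group means -> zero fold change, not DE
  flat <- matrix(rep(c(1, 1, 1, 1, 1, 1, 1, 1), 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), colnames(base)))
  res0 <- simple_de_test(flat, groups, c("GG", "VV"))
  expect_equal(res0$log2fc, c(0, 0))
  expect_false(any(res0$is_de))
  expect_error(simple_de_test(base, c("VV", rep("GG", 7)), c("GG", "VV")),
               "at least 2 samples")
})

test_that("label-permuted null data controls the raw DE error rate", {
  set.seed(9)
  n <- 400; groups <- rep(c("A", "B"), each = 4)
  m <- matrix(rnorm(n * 8), n,
              dimnames = list(paste0("g", 1:n), paste0("s", 1:8)))
  res <- simple_de_test(m, groups, c("A", "B"))
  rate <- mean(res$p_value <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})
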