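anchors3 <- tibble::tibble(marker_id = c("m1", "m2", "m3"), chrom = "chr1",
                           cm_a = c(0, 10, 20), cm_b = c(0, 20, 25),
                           phys_bp = c(1000, 11000, 16000))

test_that("map conversion interpolates piecewise-linearly", {
  a2 <- anchors3[1:2, ]
  expect_equal(convert_map_position(5, "chr1", a2), 10)
  expect_equal(convert_map_position(10, "chr1", a2), 20)   # at an anchor
  expect_equal(convert_map_position(15, "chr1", anchors3), 22.5)
  # terminal-segment extrapolation on both sides
  expect_equal(convert_map_position(25, "chr1", anchors3), 27.5)
  expect_equal(convert_map_position(-2, "chr1", a2), -4)
  expect_error(convert_map_position(5, "chr2", anchors3), "at least 2")
  bad <- anchors3; bad$cm_b <- c(0, 20, 15)
  expect_error(convert_map_position(5, "chr1", bad), "monotone")
})

test_that("map conversion is monotone and exact at anchors", {
  set.seed(20)
  cm_a <- sort(runif(8, 0, 100))
  cm_b <- cumsum(runif(8, 0, 10))
  anc <- tibble::tibble(chrom = "c", cm_a = cm_a, cm_b = cm_b)
  q <- sort(runif(50, -5, 105))
  out <- convert_map_position(q, "c", anc)
  expect_true(all(diff(out) >= -1e-12))
  expect_equal(convert_map_position(cm_a, "c", anc), cm_b, tolerance = 1e-12)
  # A -> B -> A round trip at anchors is exact
  a_vals <- cm_a; b_vals <- cm_b
  anc_rev <- tibble::tibble(chrom = "c", cm_a = b_vals, cm_b = a_vals)
  expect_equal(convert_map_position(cm_b, "c", anc_rev), cm_a,
               tolerance = 1e-12)
})

test_that("genetic-to-physical conversion respects anchors", {
  a2 <- tibble::tibble(chrom = "chr1", cm_b = c(0, 10),
                       phys_bp = c(1000, 11000))
  expect_equal(map_to_physical(5, "chr1", a2), 6000)
  expect_equal(map_to_physical(anchors3$cm_b, "chr1", anchors3),
               anchors3$phys_bp)
  bad <- anchors3; bad$phys_bp <- c(1000, 11000, 9000)
  expect_error(map_to_physical(5, "chr1", bad), "non-monotone")
})

mk_panel <- function(test_calls, pos = seq(1000, 10000, by = 1000),
                     chrom = "chr1") {
  n <- length(pos)
  markers <- tibble::tibble(marker_id = sprintf("m%02d", seq_len(n)),
                            chrom = chrom, pos_bp = as.integer(pos))
  calls <- cbind(test_calls,
                 matrix("V", n, 2), matrix("G", n, 2))
  colnames(calls) <- c(colnames(test_calls), "cv1", "cv2", "cg1", "cg2")
  rownames(calls) <- markers$marker_id
  roles <- stats::setNames(c(rep("test", ncol(test_calls)),
                             "control_V", "control_V",
                             "control_G", "control_G"),
                           colnames(calls))
  marker_panel(markers, calls, roles)
}

test_that("a single flagged marker yields the between-flank interval", {
  tc <- matrix("G", 10, 2, dimnames = list(NULL, c("t1", "t2")))
  tc[5, ] <- "V"  # marker at 5000
  scan <- scan_introgression(mk_panel(tc))
  expect_equal(nrow(scan$loci), 1)
  expect_equal(scan$loci$start, 4001L)
  expect_equal(scan$loci$end, 5999L)
  expect_equal(scan$flagged, "m05")
  expect_equal(scan$n_usable, 10L)
})

test_that("test-sample disagreement or missingness blocks flagging", {
  tc <- matrix("G", 10, 2, dimnames = list(NULL, c("t1", "t2")))
  tc[5, 1] <- "V"              # samples disagree
  tc[7, ] <- c("V", NA)        # missing call
  scan <- scan_introgression(mk_panel(tc))
  expect_equal(nrow(scan$loci), 0)
  expect_length(scan$flagged, 0)
})

test_that("control-inconsistent markers are unusable, never flagged", {
  tc <- matrix("V", 10, 2, dimnames = list(NULL, c("t1", "t2")))
  panel <- mk_panel(tc)
  panel$calls[3, "cv1"] <- "G"   # reference control fails
  panel$calls[4, "cg2"] <- NA    # missing control
  scan <- scan_introgression(panel)
  expect_equal(scan$n_usable, 8L)
  expect_false(any(c("m03", "m04") %in% scan$flagged))
})

test_that("adjacent flagged markers merge and chromosome ends extend", {
  tc <- matrix("G", 10, 2, dimnames = list(NULL, c("t1", "t2")))
  tc[4:5, ] <- "V"   # adjacent run -> one locus
  tc[10, ] <- "V"    # terminal marker -> extends to chromosome end
  scan <- scan_introgression(mk_panel(tc),
                             chrom_lengths = c(chr1 = 12000))
  expect_equal(nrow(scan$loci), 2)
  expect_equal(scan$loci$start, c(3001L, 9001L))
  expect_equal(scan$loci$end, c(5999L, 12000L))
  expect_equal(scan$loci$n_markers, c(2L, 1L))
  # loci are disjoint and each contains a flagged marker
  expect_true(scan$loci$end[1] < scan$loci$start[2])
})

test_that("genes overlap loci by at least one base", {
  genes <- make_genes(c("g1", "g2", "g3"), "chr1",
                      c(100, 100, 301), c(200, 149, 400))
  locus <- tibble::tibble(chrom = "chr1", start = 150L, end = 300L)
  hit <- genes_in_locus(locus, genes)
  expect_setequal(hit$gene_id, "g1")
  expect_equal(nrow(genes_in_locus(
    tibble::tibble(chrom = "chr2", start = 1L, end = 10L), genes)), 0)
})

test_that("gene-set overlap proportions are exact", {
  o <- gene_set_overlap(c("1", "2", "3", "4"), c("3", "4", "5", "6"))
  expect_equal(o$n_intersection, 2)
  expect_equal(o$frac_union, 2 / 6)
  expect_equal(o$frac_a, 0.5)
  expect_equal(gene_set_overlap(letters, letters)$frac_union, 1)
  expect_equal(gene_set_overlap(letters[1:3], letters[4:6])$n_intersection, 0)
})

test_that("locus enrichment matches the hypergeometric by enumeration", {
  u <- sprintf("g%02d", 1:10)
  res <- locus_enrichment(u[1:4], u[1:5], u)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  # enumeration oracle over all C(N, n) draws for small universes
  enum_p <- function(hits, locus, universe) {
    draws <- utils::combn(length(universe), length(hits))
    in_locus <- universe %in% locus
    k_obs <- sum(hits %in% locus)
    mean(apply(draws, 2, function(d) sum(in_locus[d])) >= k_obs)
  }
  set.seed(21)
  for (i in 1:5) {
    uni <- sprintf("x%02d", 1:12)
    locus <- sample(uni, 5)
    hits <- sample(uni, 4)
    got <- locus_enrichment(hits, locus, uni)
    expect_equal(got$p_value, enum_p(hits, locus, uni), tolerance = 1e-10)
  }
  expect_error(locus_enrichment("zz", u[1:3], u), "outside the universe")
  expect_error(locus_enrichment(u[1], u[1:3], character(0)), "empty universe")
})
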