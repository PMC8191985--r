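# Multi-sample VCF ingestion. Only site coordinates, alleles and GT calls are
# used downstream; genotypes are normalized to unordered "i/j" strings.

#' Read jointly genotyped variant sites from a VCF
#'
#' Parses a VCF v4.x file into a site table. One row per record; positions are
#' 1-based; multi-allelic records are preserved with all ALT alleles. Genotypes
#' are normalized: phase separators become `/`, allele indices are sorted
#' within each call (calls are unordered pairs), and any call containing `.`
#' becomes missing (`NA`).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt` (comma-separated
#'   ALT alleles, as in the VCF), `n_alt`, and a character matrix column `gt`
#'   (sites x samples, colnames are sample IDs in header order). The sample
#'   IDs are also stored in `attr(, "samples")`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          n_alt = integer())
  if (is.null(fix) || nrow(fix) == 0L) {
    empty$gt <- matrix(character(0), nrow = 0, ncol = 0)
    attr(empty, "samples") <- character(0)
    return(empty)
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  samples <- colnames(gt_raw)
  alts <- as.character(fix[, "ALT"])
  n_alt <- lengths(strsplit(alts, ",", fixed = TRUE))
  gt <- normalize_gt(gt_raw, n_alt)
  out <- tibble::tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = alts,
    n_alt = as.integer(n_alt))
  if (any(is.na(out$pos) | out$pos < 1)) {
    bad <- which(is.na(out$pos) | out$pos < 1)[1]
    stop("malformed POS at VCF record ", bad)
  }
  if (any(is.na(out$alt) | !nzchar(out$alt)))
    stop("VCF record with empty ALT at record ",
         which(is.na(out$alt) | !nzchar(out$alt))[1])
  out$gt <- gt
  attr(out, "samples") <- samples
  out
}

# Normalize a raw GT matrix: "0|1" -> "0/1", indices sorted, missing -> NA.
# Errors name the offending record (row) for traceability.
normalize_gt <- function(gt_raw, n_alt) {
  gt <- gt_raw
  gt[] <- gsub("|", "/", gt_raw, fixed = TRUE)
  flat <- as.vector(gt)
  miss <- is.na(flat) | grepl(".", flat, fixed = TRUE)
  ok <- miss | grepl("^[0-9]+(/[0-9]+)?$", flat)
  if (!all(ok)) {
    bad <- arrayInd(which(!ok)[1], dim(gt))
    stop("malformed genotype '", flat[!ok][1], "' at VCF record ", bad[1],
         ", sample ", colnames(gt_raw)[bad[2]])
  }
  flat[miss] <- NA_character_
  parts <- strsplit(flat[!miss], "/", fixed = TRUE)
  norm <- vapply(parts, function(p) {
    i <- sort(as.integer(p))
    if (length(i) == 1L) i <- c(i, i)  # haploid call treated as homozygous
    paste(i, collapse = "/")
  }, character(1))
  flat[!miss] <- norm
  out <- matrix(flat, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = list(NULL, colnames(gt_raw)))
  # allele indices must not exceed the number of ALT alleles of their record
  max_idx <- suppressWarnings(
    apply(out, 2, function(col) {
      v <- rep(0L, length(col))
      has <- !is.na(col)
      v[has] <- vapply(strsplit(col[has], "/", fixed = TRUE),
                       function(p) max(as.integer(p)), integer(1))
      v
    }))
  max_idx <- matrix(max_idx, nrow = nrow(out))
  over <- which(max_idx > n_alt, arr.ind = TRUE)
  if (nrow(over) > 0L)
    stop("genotype allele index exceeds ALT count at VCF record ", over[1, 1])
  out
}

#' Write variant sites to a minimal VCF
#'
#' Emits a VCF v4.2 file containing CHROM, POS, REF, ALT and per-sample GT.
#' The complement of [read_vcf()] for simulated data.
#'
#' @param sites Site tibble as returned by [read_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path) {
  samples <- attr(sites, "samples")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(sites) > 0L) {
    gt <- sites$gt
    gt[is.na(gt)] <- "./."
    lines <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                   "PASS", ".", "GT", sep = "\t")
    lines <- paste(lines, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
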