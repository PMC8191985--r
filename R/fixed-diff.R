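# Fixed-difference SNP classification between two inbred parental groups.
# A site qualifies only if it is a biallelic single-base SNP, homozygous
# reference in every group-A sample and homozygous (first) alternate in every
# group-B sample. Missing or heterozygous calls disqualify the site: the rule
# requires homozygosity in all replicates of each inbred line.

#' Classify jointly genotyped sites against the fixed-difference rule
#'
#' @param sites Site tibble from [read_vcf()].
#' @param group_a,group_b Disjoint, non-empty character vectors of sample IDs;
#'   group A carries the reference allele, group B the alternate.
#' @return Character vector, one of `"fixed_different"`, `"not_fixed"`,
#'   `"not_biallelic_snp"` per site. Multi-allelic or indel records are
#'   `"not_biallelic_snp"`; sites where group B is homozygous for a non-first
#'   ALT are excluded and counted in `attr(, "n_nonfirst_alt")`.
#' @export
classify_sites <- function(sites, group_a, group_b) {
  samples <- attr(sites, "samples")
  check_groups(group_a, group_b, samples)
  n <- nrow(sites)
  if (n == 0L) {
    out <- character(0)
    attr(out, "n_nonfirst_alt") <- 0L
    return(out)
  }
  snp <- sites$n_alt == 1L &
    sites$ref %in% c("A", "C", "G", "T") &
    sites$alt %in% c("A", "C", "G", "T")
  ga <- sites$gt[, group_a, drop = FALSE]
  gb <- sites$gt[, group_b, drop = FALSE]
  a_homref <- rowSums(ga == "0/0", na.rm = TRUE) == length(group_a) &
    rowSums(is.na(ga)) == 0L
  b_homalt <- rowSums(gb == "1/1", na.rm = TRUE) == length(group_b) &
    rowSums(is.na(gb)) == 0L
  out <- ifelse(!snp, "not_biallelic_snp",
                ifelse(a_homref & b_homalt, "fixed_different", "not_fixed"))
  # counter: would-be-fixed sites where group B is homozygous for ALT j > 1
  multi <- sites$n_alt > 1L
  nonfirst <- 0L
  if (any(multi)) {
    gbm <- gb[multi, , drop = FALSE]
    hom_nonfirst <- apply(gbm, 1, function(r) {
      if (anyNA(r)) return(FALSE)
      u <- unique(r)
      length(u) == 1L && grepl("^([2-9]|[1-9][0-9]+)/", u) &&
        sub("/.*", "", u) == sub(".*/", "", u)
    })
    am <- a_homref[multi]
    nonfirst <- sum(hom_nonfirst & am)
  }
  attr(out, "n_nonfirst_alt") <- as.integer(nonfirst)
  out
}

#' Classify a single site
#' @param site One-row site tibble.
#' @inheritParams classify_sites
#' @return Length-1 character classification.
#' @export
classify_site <- function(site, group_a, group_b) {
  stopifnot(nrow(site) == 1L)
  as.character(classify_sites(site, group_a, group_b))
}

check_groups <- function(group_a, group_b, samples) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both sample groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("sample groups must be disjoint")
  unknown <- setdiff(c(group_a, group_b), samples)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Build the set of fixed-difference SNPs between two parental groups
#'
#' Applies [classify_sites()] and keeps exactly the `fixed_different` sites,
#' sorted by (chrom, pos). Deterministic for any input order.
#'
#' @inheritParams classify_sites
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt` (single bases).
#'   Attributes: `groups` (the labels used), `n_input`, `n_not_biallelic`,
#'   `n_nonfirst_alt`.
#' @export
build_fixed_difference_set <- function(sites, group_a, group_b) {
  cls <- classify_sites(sites, group_a, group_b)
  keep <- which(cls == "fixed_different")
  out <- tibble::tibble(chrom = sites$chrom[keep], pos = sites$pos[keep],
                        ref = sites$ref[keep], alt = sites$alt[keep])
  out <- dplyr::arrange(dplyr::distinct(out), .data$chrom, .data$pos)
  dup <- duplicated(out[, c("chrom", "pos")])
  if (any(dup)) {
    d <- out[dup, ]
    stop("conflicting alleles at duplicated position(s): ",
         paste(paste0(d$chrom, ":", d$pos), collapse = ", "))
  }
  attr(out, "groups") <- list(group_a = group_a, group_b = group_b)
  attr(out, "n_input") <- nrow(sites)
  attr(out, "n_not_biallelic") <- sum(cls == "not_biallelic_snp")
  attr(out, "n_nonfirst_alt") <- attr(cls, "n_nonfirst_alt")
  out
}

#' Write / read a fixed-difference set as TSV (chrom, pos, ref, alt)
#' @param diffs Fixed-difference tibble.
#' @param path File path.
#' @return `path` invisibly (writer); the tibble (reader).
#' @export
write_fixed_diff <- function(diffs, path) {
  utils::write.table(as.data.frame(diffs[, c("chrom", "pos", "ref", "alt")]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixed_diff
#' @export
read_fixed_diff <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  validate_fixed_diff(tibble::tibble(chrom = as.character(df$chrom),
                                     pos = as.integer(df$pos),
                                     ref = df$ref, alt = df$alt))
}

validate_fixed_diff <- function(diffs) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(diffs)))
  if (anyDuplicated(diffs[, c("chrom", "pos")]))
    stop("duplicated (chrom, pos) in fixed-difference set")
  ok <- diffs$ref %in% c("A", "C", "G", "T") &
    diffs$alt %in% c("A", "C", "G", "T") & diffs$ref != diffs$alt
  if (!all(ok)) stop("fixed-difference entries must be single differing bases")
  if (any(diffs$pos < 1)) stop("positions must be >= 1")
  diffs
}
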