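# Pseudo-reference construction: substitute the alternate base at every
# fixed-difference SNP position. SNP-only edits keep coordinates (and the
# shared gene annotation) valid on both references.

#' Build a pseudo reference by substituting alternate alleles
#'
#' Every entry of `diffs` replaces the reference base at its position with the
#' alternate base. The reference base at each position must match the entry's
#' `ref` (case-insensitive): a mismatch aborts with the offending `chrom:pos`,
#' guarding against assembly/VCF version skew. Two entries at one position are
#' an error, not last-wins.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param diffs Fixed-difference tibble (`chrom`, `pos`, `ref`, `alt`).
#' @return Genome with identical names and lengths; only diff positions edited.
#' @export
build_pseudo_reference <- function(genome, diffs) {
  validate_genome(genome)
  diffs <- validate_fixed_diff(diffs)
  missing_chr <- setdiff(unique(diffs$chrom), names(genome))
  if (length(missing_chr))
    stop("diff chrom(s) absent from genome: ", paste(missing_chr, collapse = ", "))
  out <- genome
  for (chrom in unique(diffs$chrom)) {
    d <- diffs[diffs$chrom == chrom, ]
    r <- charToRaw(genome[[chrom]])
    if (any(d$pos > length(r)))
      stop("position beyond sequence end at ", chrom, ":",
           d$pos[d$pos > length(r)][1])
    have <- toupper(rawToChar(r[d$pos], multiple = TRUE))
    bad <- have != d$ref
    if (any(bad))
      stop("reference-base mismatch at ",
           paste(paste0(chrom, ":", d$pos[bad], " (genome ", have[bad],
                        ", expected ", d$ref[bad], ")"), collapse = ", "))
    r[d$pos] <- charToRaw(paste(d$alt, collapse = ""))
    out[[chrom]] <- rawToChar(r)
  }
  out
}

#' Verify a pseudo reference against its fixed-difference set
#'
#' Recomputes per-position differences between the original and pseudo
#' genomes and compares them with `diffs`. A clean report has no unexpected
#' edits and no unrealized diffs.
#'
#' @param original,pseudo Genomes with identical sequence names and lengths.
#' @param diffs Fixed-difference tibble.
#' @return List with `clean` (logical), `unexpected` (tibble of positions
#'   differing outside `diffs`), `unrealized` (tibble of diffs whose alternate
#'   base is not present in `pseudo`).
#' @export
verify_pseudo_reference <- function(original, pseudo, diffs) {
  if (!identical(sort(names(original)), sort(names(pseudo))))
    stop("sequence-name sets differ between genomes")
  lens <- nchar(original[names(original)]) == nchar(pseudo[names(original)])
  if (!all(lens))
    stop("sequence length mismatch for: ",
         paste(names(original)[!lens], collapse = ", "))
  observed <- genome_differences(original, pseudo)
  key <- function(x) paste(x$chrom, x$pos)
  diffs <- validate_fixed_diff(diffs)
  unexpected <- observed[!key(observed) %in% key(diffs), , drop = FALSE]
  realized <- observed[key(observed) %in% key(diffs), , drop = FALSE]
  merged <- dplyr::left_join(diffs, realized,
                             by = c("chrom", "pos"), suffix = c("", "_obs"))
  unrealized <- merged[is.na(merged$alt_obs) | merged$alt_obs != merged$alt |
                         merged$ref_obs != merged$ref,
                       c("chrom", "pos", "ref", "alt")]
  list(clean = nrow(unexpected) == 0L && nrow(unrealized) == 0L,
       unexpected = tibble::as_tibble(unexpected),
       unrealized = tibble::as_tibble(unrealized))
}

# brute-force per-position comparison of two equal-length genomes
genome_differences <- function(a, b) {
  res <- lapply(names(a), function(chrom) {
    ra <- charToRaw(a[[chrom]]); rb <- charToRaw(b[[chrom]])
    idx <- which(ra != rb)
    tibble::tibble(chrom = chrom, pos = idx,
                   ref = toupper(rawToChar(ra[idx], multiple = TRUE)),
                   alt = toupper(rawToChar(rb[idx], multiple = TRUE)))
  })
  dplyr::bind_rows(res)
}

#' Swap ref/alt roles of a fixed-difference set
#'
#' Applying [build_pseudo_reference()] with the swapped set to a pseudo
#' reference returns the original genome (involution).
#' @param diffs Fixed-difference tibble.
#' @return Tibble with `ref` and `alt` exchanged.
#' @export
swap_fixed_diff <- function(diffs) {
  tibble::tibble(chrom = diffs$chrom, pos = diffs$pos,
                 ref = diffs$alt, alt = diffs$ref)
}
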