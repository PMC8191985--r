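# Readers/writers for the standard formats the pipeline touches. Internal
# coordinates are 1-based inclusive everywhere (VCF-native); BED is converted
# at the boundary.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the `A,C,G,T,N` alphabet.
#' The genome is represented as a named character vector (one element per
#' sequence, names taken from the first whitespace-delimited token of each
#' header).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (length(out) == 0L) return(stats::setNames(character(0), character(0)))
  if (any(!nzchar(names(out)))) stop("FASTA contains a record with an empty name")
  if (anyDuplicated(names(out)))
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("illegal characters (outside A,C,G,T,N) in sequence(s): ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Write a reference genome to FASTA
#'
#' @param genome Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @param line_width Maximum sequence-line width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  validate_genome(genome)
  set <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

validate_genome <- function(genome) {
  if (length(genome) == 0L) return(invisible(genome))
  if (is.null(names(genome)) || any(!nzchar(names(genome))) ||
      anyDuplicated(names(genome)))
    stop("genome must have unique, non-empty sequence names")
  if (any(grepl("[^ACGTN]", genome)))
    stop("genome sequences contain characters outside A,C,G,T,N")
  invisible(genome)
}

#' Read gene models from GFF3 or BED12
#'
#' Returns one row per gene with 1-based inclusive coordinates. BED input
#' (0-based half-open) is converted at the boundary. `exonic_length` is the
#' length of the union of exon intervals; genes without exon features fall
#' back to the gene span (an approximation used for FPKM lengths).
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed12"`.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `exonic_length`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  empty <- tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), exonic_length = integer())
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (length(gr) == 0L) return(empty)

  if (format == "bed12") {
    blocks <- if (!is.null(gr$blocks)) {
      vapply(gr$blocks, function(b) sum(IRanges::width(b)), integer(1))
    } else {
      GenomicRanges::width(gr)
    }
    genes <- tibble::tibble(
      gene_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      exonic_length = as.integer(blocks))
  } else {
    type <- as.character(gr$type)
    g <- gr[type == "gene"]
    if (length(g) == 0L) return(empty)
    gid <- as.character(g$ID)
    if (any(is.na(gid) | !nzchar(gid)))
      stop("GFF3 gene feature without an ID attribute")
    # exon Parent may point at the gene directly or at an mRNA child
    ex <- gr[type == "exon"]
    exon_len <- stats::setNames(rep(NA_integer_, length(gid)), gid)
    if (length(ex) > 0L) {
      tx <- gr[type %in% c("mRNA", "transcript")]
      tx_parent <- if (length(tx)) stats::setNames(
        vapply(tx$Parent, function(p) p[1], character(1)),
        as.character(tx$ID)) else character(0)
      ex_parent <- vapply(ex$Parent, function(p) p[1], character(1))
      ex_gene <- ifelse(ex_parent %in% names(tx_parent),
                        unname(tx_parent[ex_parent]), ex_parent)
      keep <- ex_gene %in% gid
      if (any(keep)) {
        red <- GenomicRanges::reduce(
          GenomicRanges::split(ex[keep], ex_gene[keep]))
        lens <- vapply(red, function(x) sum(GenomicRanges::width(x)), integer(1))
        exon_len[names(lens)] <- as.integer(lens)
      }
    }
    genes <- tibble::tibble(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      exonic_length = ifelse(is.na(exon_len[gid]),
                             GenomicRanges::end(g) - GenomicRanges::start(g) + 1L,
                             exon_len[gid]))
  }
  genes$strand[genes$strand == "*"] <- "."
  if (any(genes$end < genes$start)) stop("gene feature with end < start")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  genes$exonic_length <- as.integer(pmax(genes$exonic_length, 1L))
  genes
}

#' Write gene models to BED (0-based half-open) for interoperability
#'
#' @param genes Gene tibble from [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                   end = genes$end, name = genes$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ase_table_cols <- c("contig", "position", "refAllele", "altAllele",
                    "refCount", "altCount", "totalCount")

#' Read a per-SNP allele-count table
#'
#' Reads the tab-separated output format of an allele counter (columns
#' `contig, position, refAllele, altAllele, refCount, altCount, totalCount`).
#' `totalCount` is re-derived as `refCount + altCount` on ingestion (reads
#' supporting other bases are ignored); a stored total below that sum is a
#' validation error.
#'
#' @param path TSV file.
#' @param sample_id,cross,dataset Optional labels attached to every record;
#'   `cross` must be `"VG"` (reference-line mother) or `"GV"` when given.
#' @return Tibble of allele-count records with columns `sample_id`, `cross`,
#'   `dataset`, `chrom`, `pos`, `ref_base`, `alt_base`, `ref_count`,
#'   `alt_count`, `total_count`.
#' @export
read_ase_table <- function(path, sample_id = NA_character_,
                           cross = NA_character_, dataset = NA_character_) {
  if (!is.na(cross)) stopifnot(cross %in% c("VG", "GV"))
  # colClasses guards against "T" alleles being read as logicals
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(ase_table_cols, names(df))
  if (length(missing_cols))
    stop("allele-count table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("position", "refCount", "altCount", "totalCount"))
    df[[col]] <- as.numeric(df[[col]])
  if (nrow(df) == 0L) {
    return(tibble::tibble(sample_id = character(), cross = character(),
                          dataset = character(), chrom = character(),
                          pos = integer(), ref_base = character(),
                          alt_base = character(), ref_count = integer(),
                          alt_count = integer(), total_count = integer()))
  }
  if (any(df$refCount < 0 | df$altCount < 0 | df$totalCount < 0))
    stop("negative count in allele-count table")
  if (any(df$totalCount < df$refCount + df$altCount))
    stop("totalCount < refCount + altCount in allele-count table")
  if (any(df$position < 1)) stop("position must be >= 1")
  bases_ok <- df$refAllele %in% c("A", "C", "G", "T") &
    df$altAllele %in% c("A", "C", "G", "T")
  if (!all(bases_ok)) stop("non-SNP allele in allele-count table")
  tibble::tibble(
    sample_id = sample_id, cross = cross, dataset = dataset,
    chrom = as.character(df$contig), pos = as.integer(df$position),
    ref_base = df$refAllele, alt_base = df$altAllele,
    ref_count = as.integer(df$refCount), alt_count = as.integer(df$altCount),
    total_count = as.integer(df$refCount + df$altCount))
}

#' Write allele-count records back to the tabular interchange format
#' @param records Record tibble as returned by [read_ase_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ase_table <- function(records, path) {
  df <- data.frame(contig = records$chrom, position = records$pos,
                   refAllele = records$ref_base, altAllele = records$alt_base,
                   refCount = records$ref_count, altCount = records$alt_count,
                   totalCount = records$total_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level count matrix (gene_id + one column per sample)
#' @param path TSV file with a `gene_id` column.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_counts_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("counts table must have a gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative counts in matrix")
  m
}
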