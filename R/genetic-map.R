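# Piecewise-linear conversion between two genetic maps and from genetic to
# physical coordinates. A per-interval conversion ratio generalizes a single
# map-wide ratio (and reduces to it with two anchors).

# linear interpolation through (ax, ay) with terminal-segment extrapolation
piecewise_linear <- function(x, ax, ay) {
  ord <- order(ax)
  ax <- ax[ord]; ay <- ay[ord]
  if (anyDuplicated(ax)) stop("duplicated anchor positions")
  n <- length(ax)
  vapply(x, function(q) {
    if (q <= ax[1]) {
      slope <- (ay[2] - ay[1]) / (ax[2] - ax[1])
      ay[1] + (q - ax[1]) * slope
    } else if (q >= ax[n]) {
      slope <- (ay[n] - ay[n - 1]) / (ax[n] - ax[n - 1])
      ay[n] + (q - ax[n]) * slope
    } else {
      i <- findInterval(q, ax)
      ay[i] + (q - ax[i]) * (ay[i + 1] - ay[i]) / (ax[i + 1] - ax[i])
    }
  }, numeric(1))
}

check_anchor_cols <- function(anchors, cols) {
  miss <- setdiff(cols, names(anchors))
  if (length(miss)) stop("anchor table missing column(s): ",
                         paste(miss, collapse = ", "))
  invisible(anchors)
}

#' Convert a genetic-map position from map A to map B
#'
#' Piecewise-linear interpolation between the flanking anchors on the same
#' chromosome; queries outside the anchor range extrapolate with the terminal
#' segment's ratio. Anchor `cm_b` must be non-decreasing in `cm_a`.
#'
#' @param pos_cm Query position(s) in map-A centimorgans.
#' @param chrom Chromosome of the query.
#' @param anchors Tibble with columns `chrom`, `cm_a`, `cm_b` (and optionally
#'   `marker_id`, `phys_bp`).
#' @return Position(s) in map-B centimorgans.
#' @export
convert_map_position <- function(pos_cm, chrom, anchors) {
  check_anchor_cols(anchors, c("chrom", "cm_a", "cm_b"))
  a <- anchors[anchors$chrom == chrom, ]
  if (nrow(a) < 2) stop("need at least 2 anchors on chromosome ", chrom)
  a <- a[order(a$cm_a), ]
  if (any(a$cm_a < 0) || any(a$cm_b < 0)) stop("cM positions must be >= 0")
  if (is.unsorted(a$cm_b)) stop("map-B anchor positions are not monotone ",
                                "non-decreasing on chromosome ", chrom)
  piecewise_linear(pos_cm, a$cm_a, a$cm_b)
}

#' Convert a map-B genetic position to a physical position
#'
#' Piecewise-linear cM to bp interpolation through anchors carrying physical
#' positions; physical anchor positions must be monotone in `cm_b`.
#'
#' @param pos_cm Query position(s) in map-B centimorgans.
#' @param chrom Chromosome.
#' @param anchors Tibble with columns `chrom`, `cm_b`, `phys_bp`.
#' @return Physical position(s) in bp.
#' @export
map_to_physical <- function(pos_cm, chrom, anchors) {
  check_anchor_cols(anchors, c("chrom", "cm_b", "phys_bp"))
  a <- anchors[anchors$chrom == chrom & !is.na(anchors$phys_bp), ]
  if (nrow(a) < 2) stop("need at least 2 physically anchored markers on ",
                        chrom)
  a <- a[order(a$cm_b), ]
  if (is.unsorted(a$phys_bp)) {
    i <- which(diff(a$phys_bp) < 0)[1]
    stop("non-monotone physical anchors on ", chrom, " between cM ",
         a$cm_b[i], " and ", a$cm_b[i + 1])
  }
  piecewise_linear(pos_cm, a$cm_b, a$phys_bp)
}
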