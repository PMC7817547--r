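#' Construct a marker map
#'
#' A marker map is an ordered table of genotyping markers with 1-based
#' physical positions in base pairs. Positions must be strictly increasing
#' within each chromosome and marker ids unique; rows are stored sorted by
#' chromosome then position.
#'
#' @param marker character vector of marker ids
#' @param chrom chromosome labels (recycled if length 1)
#' @param pos_bp positive integer positions in bp
#' @return a `data.frame` of class `marker_map` with columns
#'   `marker`, `chrom`, `pos_bp`
#' @examples
#' marker_map(c("m1", "m2", "m3"), "4", c(7180000L, 8290453L, 13079020L))
#' @export
marker_map <- function(marker, chrom, pos_bp) {
  hf_assert(length(marker) >= 1, "marker map needs at least one marker")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(marker))
  hf_assert(length(marker) == length(chrom) && length(marker) == length(pos_bp),
            "marker, chrom and pos_bp must have equal length")
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  pos_bp <- as.numeric(pos_bp)
  hf_assert(!anyNA(marker) && !anyNA(chrom) && !anyNA(pos_bp),
            "marker map must not contain missing values")
  hf_assert(all(pos_bp > 0 & pos_bp == round(pos_bp)),
            "positions must be positive integers (bp)")
  hf_assert(!anyDuplicated(marker), "marker ids must be unique")
  ord <- order(chrom, pos_bp)
  x <- data.frame(marker = marker[ord], chrom = chrom[ord],
                  pos_bp = pos_bp[ord], stringsAsFactors = FALSE)
  dup <- stats::ave(x$pos_bp, x$chrom, FUN = function(p) duplicated(p))
  hf_assert(!any(dup > 0),
            "positions must be strictly increasing within a chromosome")
  class(x) <- c("marker_map", "data.frame")
  x
}

# markers of one chromosome, optionally clipped to [start, end] (closed)
map_chrom <- function(map, chrom = NULL, region = NULL) {
  hf_assert(inherits(map, "marker_map") ||
              all(c("marker", "chrom", "pos_bp") %in% names(map)),
            "map must be a marker_map")
  if (is.null(chrom)) {
    chroms <- unique(map$chrom)
    hf_assert(length(chroms) == 1L,
              "map has several chromosomes; supply `chrom`")
    chrom <- chroms
  }
  sub <- map[map$chrom == chrom, , drop = FALSE]
  hf_assert(nrow(sub) >= 2, "at least 2 markers per chromosome are required")
  if (!is.null(region)) {
    hf_assert(length(region) == 2 && region[1] < region[2],
              "region must be c(start_bp, end_bp) with start < end")
    sub <- sub[sub$pos_bp >= region[1] & sub$pos_bp <= region[2], , drop = FALSE]
    hf_assert(nrow(sub) >= 2, "fewer than 2 markers inside region")
  }
  sub
}

# snap an interval outward to the nearest flanking marker positions
snap_outward <- function(start_bp, end_bp, positions) {
  lo <- positions[positions <= start_bp]
  hi <- positions[positions >= end_bp]
  s <- if (length(lo)) max(lo) else min(positions)
  e <- if (length(hi)) min(hi) else max(positions)
  c(s, e)
}

#' Parse a genomic region string
#'
#' @param x a string `"chrom:start-end"` with bp integer bounds, e.g.
#'   `"4:7180000-13079020"`
#' @return list with `chrom`, `start_bp`, `end_bp`
#' @export
parse_region <- function(x) {
  hf_assert(is.character(x) && length(x) == 1L, "region must be one string")
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  hf_assert(length(m) == 4, sprintf("malformed region '%s' (want chrom:start-end)", x))
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  hf_assert(start < end, "region start must be < end")
  list(chrom = m[2], start_bp = start, end_bp = end)
}
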