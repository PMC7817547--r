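ALLELE_CODES <- c("A", "B", "H", "U")

#' Construct a genotype table
#'
#' Line-by-marker allele calls aligned to a marker map. Codes: `A` (first
#' parental homozygote), `B` (second parental homozygote), `H`
#' (heterozygote), `U` (missing/unknown).
#'
#' @param line_id character vector of line ids
#' @param calls character matrix (lines x markers) of allele codes
#' @param map a [marker_map()]; column order of `calls` must match `map$marker`
#' @return data.frame of class `genotype_table`: `line_id` plus one column per
#'   marker
#' @export
genotype_table <- function(line_id, calls, map) {
  calls <- as.matrix(calls)
  hf_assert(nrow(calls) == length(line_id),
            "one row of calls per line is required")
  hf_assert(ncol(calls) == nrow(map),
            sprintf("call matrix has %d columns but map has %d markers",
                    ncol(calls), nrow(map)))
  if (!is.null(colnames(calls))) {
    hf_assert(identical(colnames(calls), map$marker),
              "call columns must match map markers in order")
  }
  bad <- which(matrix(!(calls %in% ALLELE_CODES), nrow = nrow(calls)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    hf_stop(sprintf(
      "invalid allele code '%s' for line '%s', marker '%s' (codes: A, B, H, U)",
      calls[bad[1, 1], bad[1, 2]], line_id[bad[1, 1]], map$marker[bad[1, 2]]))
  }
  hf_assert(!anyDuplicated(line_id), "line ids must be unique")
  x <- data.frame(line_id = as.character(line_id), calls,
                  stringsAsFactors = FALSE, check.names = FALSE)
  colnames(x) <- c("line_id", map$marker)
  class(x) <- c("genotype_table", "data.frame")
  x
}

# extract the call vector of one line aligned to the marker subset `sub`
line_calls <- function(geno, line, sub) {
  row <- geno[geno$line_id == line, , drop = FALSE]
  hf_assert(nrow(row) == 1, sprintf("line '%s' not found (or duplicated)", line))
  unlist(row[1, sub$marker], use.names = FALSE)
}

#' Heterozygous span of a line
#'
#' The residual heterozygous interval of a line, as the span of its `H`
#' marker calls. `flank = "marker"` returns the narrow span (first to last
#' `H` marker); `flank = "informative"` widens each bound to the nearest
#' informative homozygous marker (or the region bound), the genotyping
#' resolution limit of the true heterozygous segment.
#'
#' @param calls character vector of allele codes aligned to `map` order
#' @param map marker map (one chromosome)
#' @param chrom,region optional chromosome / `c(start, end)` restriction
#' @param flank `"marker"` (narrow) or `"informative"` (wide)
#' @return `c(start_bp, end_bp)` or `NULL` when the line carries no `H` call
#' @export
het_span <- function(calls, map, chrom = NULL, region = NULL,
                     flank = c("marker", "informative")) {
  flank <- match.arg(flank)
  sub <- map_chrom(map, chrom, NULL)
  hf_assert(length(calls) == nrow(sub),
            "call vector length must match number of markers")
  if (!is.null(region)) {
    keep <- sub$pos_bp >= region[1] & sub$pos_bp <= region[2]
    sub <- sub[keep, , drop = FALSE]
    calls <- calls[keep]
  }
  h <- which(calls == "H")
  if (!length(h)) return(NULL)
  lo <- min(h); hi <- max(h)
  if (flank == "marker") return(c(sub$pos_bp[lo], sub$pos_bp[hi]))
  hom_left <- which(calls %in% c("A", "B") & seq_along(calls) < lo)
  hom_right <- which(calls %in% c("A", "B") & seq_along(calls) > hi)
  s <- if (length(hom_left)) sub$pos_bp[max(hom_left)] else sub$pos_bp[1]
  e <- if (length(hom_right)) sub$pos_bp[min(hom_right)] else sub$pos_bp[nrow(sub)]
  c(s, e)
}

# fraction of missing (U) calls within the region
missing_fraction <- function(calls) mean(calls == "U")

#' Heterozygous blocks of a line
#'
#' Like [het_span()] but returns every maximal run of `H` calls separately
#' (a double recombinant carries two blocks separated by a homozygous gap).
#' A non-segregating verdict excludes the causal locus from each het block,
#' not from the span across blocks, so interval subtraction must operate
#' per block. `U` calls do not interrupt a block.
#'
#' @inheritParams het_span
#' @return data.frame with `start_bp`, `end_bp`, one row per block
#'   (zero rows when the line carries no `H` call)
#' @export
het_blocks <- function(calls, map, chrom = NULL, region = NULL) {
  sub <- map_chrom(map, chrom, NULL)
  hf_assert(length(calls) == nrow(sub),
            "call vector length must match number of markers")
  if (!is.null(region)) {
    keep <- sub$pos_bp >= region[1] & sub$pos_bp <= region[2]
    sub <- sub[keep, , drop = FALSE]
    calls <- calls[keep]
  }
  inf <- which(calls != "U")
  st <- calls[inf]
  r <- rle(st == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  h <- which(r$values)
  data.frame(start_bp = sub$pos_bp[inf[starts[h]]],
             end_bp = sub$pos_bp[inf[ends[h]]])
}
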