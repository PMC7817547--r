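#' Infer recombination breakpoints of one line
#'
#' Genotyping resolves marker states, not crossover points, so each
#' breakpoint is reported as an uncertainty interval between the two nearest
#' informative (non-`U`) markers whose states differ. Missing calls widen
#' the interval to the flanking informative markers.
#'
#' @param calls character vector of allele codes (`A`, `B`, `H`, `U`)
#'   aligned to the marker order of `map` (full map, before any region clip)
#' @param map a [marker_map()]
#' @param region optional `c(start_bp, end_bp)`; only markers inside the
#'   closed interval are considered
#' @param chrom chromosome (needed when `map` spans several)
#' @param line_id optional id copied into the result
#' @return data.frame of class `breakpoint_set` with columns `line_id`,
#'   `left_pos_bp`, `right_pos_bp`, `left_state`, `right_state`; zero rows
#'   when the line carries no state transition
#' @examples
#' map <- marker_map(paste0("m", 1:4), "4", c(1e6, 2e6, 3e6, 4e6))
#' infer_breakpoints(c("A", "A", "H", "H"), map)
#' @export
infer_breakpoints <- function(calls, map, region = NULL, chrom = NULL,
                              line_id = NA_character_) {
  sub <- map_chrom(map, chrom, NULL)
  hf_assert(length(calls) == nrow(sub),
            sprintf("call vector has length %d but map has %d markers",
                    length(calls), nrow(sub)))
  hf_assert(all(calls %in% ALLELE_CODES), "invalid allele code")
  if (!is.null(region)) {
    keep <- sub$pos_bp >= region[1] & sub$pos_bp <= region[2]
    sub <- sub[keep, , drop = FALSE]
    calls <- calls[keep]
  }
  inf <- which(calls != "U")
  if (!length(inf)) hf_stop("no informative markers")
  st <- calls[inf]
  chg <- which(st[-1] != st[-length(st)])
  out <- data.frame(
    line_id = rep(line_id, length(chg)),
    left_pos_bp = sub$pos_bp[inf[chg]],
    right_pos_bp = sub$pos_bp[inf[chg + 1L]],
    left_state = st[chg],
    right_state = st[chg + 1L],
    stringsAsFactors = FALSE
  )
  class(out) <- c("breakpoint_set", "data.frame")
  out
}

#' Detect recombinant lines within a region
#'
#' A line is recombinant when its breakpoint set inside the region is
#' non-empty, i.e. it shows at least one state transition between
#' informative markers. A line uniformly heterozygous (or homozygous)
#' across the region is not a recombinant. Lines with no informative marker
#' in the region are skipped.
#'
#' @param geno a [genotype_table()]
#' @param map a [marker_map()]
#' @param region optional `c(start_bp, end_bp)`
#' @param chrom chromosome label when `map` spans several
#' @return character vector of recombinant line ids (possibly empty)
#' @export
detect_recombinants <- function(geno, map, region = NULL, chrom = NULL) {
  if (nrow(geno) == 0) return(character(0))
  sub <- map_chrom(map, chrom, NULL)
  calls <- as.matrix(geno[, sub$marker, drop = FALSE])
  if (!is.null(region)) {
    hf_assert(region[1] >= min(sub$pos_bp) && region[2] <= max(sub$pos_bp),
              "region must lie within the map span")
    keep <- sub$pos_bp >= region[1] & sub$pos_bp <= region[2]
    calls <- calls[, keep, drop = FALSE]
  }
  rec <- apply(calls, 1L, function(v) {
    st <- v[v != "U"]
    length(st) >= 2 && any(st[-1] != st[-length(st)])
  })
  geno$line_id[rec]
}

#' Select the advanced-cross pair of recombinant lines
#'
#' Picks the line recombined immediately north (breakpoint interval ending
#' at or before the target start, nearest) and the line recombined
#' immediately south (breakpoint interval starting at or after the target
#' end, nearest), such that crossing the two yields heterozygosity only over
#' the target interval. Ties are broken by smaller breakpoint-interval
#' width, then lexicographic line id.
#'
#' @param breakpoints a `breakpoint_set`-style data.frame covering all
#'   candidate lines (columns `line_id`, `left_pos_bp`, `right_pos_bp`)
#' @param target list or vector with `start_bp` and `end_bp`
#' @return named character vector `c(north = id, south = id)`
#' @export
select_arhif_pair <- function(breakpoints, target) {
  hf_assert(all(c("line_id", "left_pos_bp", "right_pos_bp") %in% names(breakpoints)),
            "breakpoints must have line_id, left_pos_bp, right_pos_bp")
  hf_assert(length(unique(breakpoints$line_id)) >= 2, "need at least 2 lines")
  start <- if (is.list(target)) target$start_bp else target[1]
  end <- if (is.list(target)) target$end_bp else target[2]
  pick <- function(cand, dist) {
    ord <- order(dist, cand$right_pos_bp - cand$left_pos_bp, cand$line_id)
    cand$line_id[ord[1]]
  }
  north <- breakpoints[breakpoints$right_pos_bp <= start, , drop = FALSE]
  if (nrow(north) == 0) hf_stop("no qualifying line on the north side")
  south <- breakpoints[breakpoints$left_pos_bp >= end, , drop = FALSE]
  if (nrow(south) == 0) hf_stop("no qualifying line on the south side")
  c(north = pick(north, start - north$right_pos_bp),
    south = pick(south, south$left_pos_bp - end))
}
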