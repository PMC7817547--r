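# Interval algebra on closed intervals with marker-position bounds.
# Intervals are rows of a 2-column matrix (start, end), start <= end, sorted
# and disjoint. A degenerate row start == end is a single surviving marker
# position (width 0): subtraction removes only the OPEN interior of a
# non-segregating het interval, so shared bound markers survive.

ivl_normalize <- function(m) {
  if (nrow(m) == 0) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], m[i, 2])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

ivl_intersect_closed <- function(m, a, b) {
  if (nrow(m) == 0) return(m)
  s <- pmax(m[, 1], a)
  e <- pmin(m[, 2], b)
  m <- cbind(s, e)[s <= e, , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

ivl_subtract_open <- function(m, a, b) {
  if (a >= b || nrow(m) == 0) return(m)  # empty open interval: no-op
  pieces <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(m))) {
    s <- m[i, 1]; e <- m[i, 2]
    # surviving left part up to a, and right part from b (closed at a and b)
    if (a >= s) pieces <- rbind(pieces, c(s, min(e, a)))
    if (b <= e) pieces <- rbind(pieces, c(max(s, b), e))
  }
  colnames(pieces) <- c("start", "end")
  ivl_normalize(pieces)
}

#' Refine the candidate interval from segregation calls
#'
#' Interval algebra of a fine-mapping campaign: the causal locus must lie in
#' the residual heterozygous interval of every line whose progeny segregate
#' for the phenotype, and outside the open interior of the heterozygous
#' interval of every line whose progeny do not. Starting from the prior
#' region, the candidate is
#' `prior` intersected with every segregating het interval (closed), minus
#' the open interior of every non-segregating het interval; bounds are
#' snapped outward to the nearest flanking marker positions. Subtraction can
#' split the region, in which case all disjoint surviving intervals are
#' returned. Inconclusive lines are ignored (and listed in `dropped`).
#' A segregating line whose het interval is disjoint from the final result
#' is recorded as a conflict, never silently dropped.
#'
#' @param lines data.frame with columns `line_id`, `start_bp`, `end_bp`,
#'   `verdict` (one het interval + segregation verdict per tested line)
#' @param map a [marker_map()]
#' @param prior `c(start_bp, end_bp)` prior interval on the map
#' @param chrom chromosome label when `map` spans several
#' @return object of class `candidate_interval`: list with `chrom`,
#'   `intervals` (data.frame `start_bp`, `end_bp`, `width_bp`), `supporting`
#'   (per-bound constraining line ids), `conflicts`, `dropped`, `n_lines`
#' @examples
#' map <- marker_map(paste0("m", 1:5), "4", (1:5) * 1e6)
#' lines <- data.frame(line_id = c("L1", "L2"),
#'                     start_bp = c(2e6, 3e6), end_bp = c(4e6, 5e6),
#'                     verdict = c("segregating", "non_segregating"))
#' refine_candidate_interval(lines, map, prior = c(1e6, 5e6))
#' @export
refine_candidate_interval <- function(lines, map, prior, chrom = NULL) {
  hf_assert(all(c("line_id", "start_bp", "end_bp", "verdict") %in% names(lines)),
            "lines must have line_id, start_bp, end_bp, verdict")
  hf_assert(nrow(lines) >= 1, "at least one tested line is required")
  hf_assert(all(lines$verdict %in%
                  c("segregating", "non_segregating", "inconclusive")),
            "unknown verdict")
  hf_assert(all(lines$start_bp < lines$end_bp | lines$start_bp == lines$end_bp),
            "het intervals must have start <= end")
  sub <- map_chrom(map, chrom, NULL)
  pos <- sub$pos_bp
  hf_assert(length(prior) == 2 && prior[1] < prior[2],
            "prior must be c(start, end) with start < end")

  dropped <- lines$line_id[lines$verdict == "inconclusive"]
  seg <- lines[lines$verdict == "segregating", , drop = FALSE]
  non <- lines[lines$verdict == "non_segregating", , drop = FALSE]

  cur <- matrix(snap_outward(prior[1], prior[2], pos), ncol = 2)
  colnames(cur) <- c("start", "end")
  for (i in seq_len(nrow(seg)))
    cur <- ivl_intersect_closed(cur, seg$start_bp[i], seg$end_bp[i])
  for (i in seq_len(nrow(non)))
    cur <- ivl_subtract_open(cur, non$start_bp[i], non$end_bp[i])

  if (nrow(cur) == 0) {
    hf_stop(paste0("inconsistent segregation calls: no candidate region ",
                   "survives (lines: ",
                   paste(c(seg$line_id, non$line_id), collapse = ", "), ")"),
            class = "hifflux_inconsistency_error",
            data = list(lines = c(seg$line_id, non$line_id)))
  }

  # snap each surviving interval outward to marker positions
  snapped <- t(apply(cur, 1L, function(r) snap_outward(r[1], r[2], pos)))
  snapped <- ivl_normalize(snapped)

  overlaps <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2
  conflicts <- character(0)
  for (i in seq_len(nrow(seg))) {
    if (!any(overlaps(seg$start_bp[i], seg$end_bp[i],
                      snapped[, 1], snapped[, 2])))
      conflicts <- c(conflicts, seg$line_id[i])
  }

  supporting <- lapply(seq_len(nrow(snapped)), function(i) {
    s <- snapped[i, 1]; e <- snapped[i, 2]
    list(
      start = unique(c(
        seg$line_id[seg$start_bp == s], non$line_id[non$end_bp == s],
        if (s <= prior[1]) "prior")),
      end = unique(c(
        seg$line_id[seg$end_bp == e], non$line_id[non$start_bp == e],
        if (e >= prior[2]) "prior"))
    )
  })

  out <- list(
    chrom = sub$chrom[1],
    intervals = data.frame(start_bp = snapped[, 1], end_bp = snapped[, 2],
                           width_bp = snapped[, 2] - snapped[, 1]),
    supporting = supporting,
    conflicts = conflicts,
    dropped = dropped,
    n_lines = nrow(lines)
  )
  class(out) <- "candidate_interval"
  out
}

#' @export
print.candidate_interval <- function(x, ...) {
  cat(sprintf("candidate interval on chromosome %s (%d tested line%s):\n",
              x$chrom, x$n_lines, if (x$n_lines == 1) "" else "s"))
  for (i in seq_len(nrow(x$intervals))) {
    cat(sprintf("  [%s, %s] bp  width %s bp (%.3f kb)\n",
                format(x$intervals$start_bp[i], big.mark = ",", scientific = FALSE),
                format(x$intervals$end_bp[i], big.mark = ",", scientific = FALSE),
                format(x$intervals$width_bp[i], big.mark = ",", scientific = FALSE),
                x$intervals$width_bp[i] / 1000))
  }
  if (length(x$conflicts))
    cat("  conflicts:", paste(x$conflicts, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  inconclusive (ignored):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
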