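# Brute-force oracle for candidate-interval refinement, independent of the
# package's interval algebra: enumerate the atomic cells of the marker grid
# (marker points and open inter-marker gaps) inside the prior, keep each
# cell iff it is consistent with every segregation call, and merge adjacent
# surviving cells. A cell is consistent when it lies inside the closed het
# interval of every segregating line and outside the open interior of every
# non-segregating line.
oracle_refine <- function(lines, positions, prior) {
  pos <- sort(positions)
  pos_in <- pos[pos >= prior[1] & pos <= prior[2]]
  # cells: (value, is_point); gaps are represented by their open bounds
  cells <- list()
  for (i in seq_along(pos_in)) {
    cells[[length(cells) + 1L]] <- list(lo = pos_in[i], hi = pos_in[i], point = TRUE)
    if (i < length(pos_in))
      cells[[length(cells) + 1L]] <- list(lo = pos_in[i], hi = pos_in[i + 1],
                                          point = FALSE)
  }
  seg <- lines[lines$verdict == "segregating", , drop = FALSE]
  non <- lines[lines$verdict == "non_segregating", , drop = FALSE]
  ok <- vapply(cells, function(cl) {
    if (cl$point) {
      x <- cl$lo
      inside_seg <- all(seg$start_bp <= x & x <= seg$end_bp)
      outside_non <- all(!(non$start_bp < x & x < non$end_bp))
      inside_seg && outside_non
    } else {
      # open gap (lo, hi): contained in closed [a,b] iff a <= lo and hi <= b;
      # disjoint from open (a,b) iff b <= lo or hi <= a
      inside_seg <- all(seg$start_bp <= cl$lo & cl$hi <= seg$end_bp)
      outside_non <- all(non$end_bp <= cl$lo | cl$hi <= non$start_bp)
      inside_seg && outside_non
    }
  }, logical(1))
  if (!any(ok)) return(NULL)
  # merge maximal runs of surviving cells; closure = [first point, last point]
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- NULL
  for (k in which(runs$values)) {
    lo <- cells[[starts[k]]]$lo
    hi <- cells[[ends[k]]]$hi
    out <- rbind(out, data.frame(start_bp = lo, end_bp = hi))
  }
  out
}

# random small refinement instance on a marker grid
random_refine_instance <- function(max_markers = 12, max_lines = 20) {
  n_mark <- sample(3:max_markers, 1)
  pos <- sort(sample(seq(1e6, 2e7, by = 1e5), n_mark))
  n_lines <- sample(1:max_lines, 1)
  resample <- function(x) x[sample.int(length(x), 1)]
  i <- vapply(seq_len(n_lines), function(k) resample(seq_len(n_mark - 1)),
              integer(1))
  j <- vapply(i, function(a) resample((a + 1):n_mark), integer(1))
  lines <- data.frame(
    line_id = sprintf("L%02d", seq_len(n_lines)),
    start_bp = pos[i], end_bp = pos[j],
    verdict = sample(c("segregating", "non_segregating"), n_lines,
                     replace = TRUE, prob = c(0.4, 0.6)),
    stringsAsFactors = FALSE)
  list(map = marker_map(sprintf("m%02d", seq_len(n_mark)), "1", pos),
       pos = pos, lines = lines,
       prior = c(pos[1], pos[n_mark]))
}

# run both routes on an instance; returns TRUE when they agree
refine_matches_oracle <- function(inst) {
  got <- tryCatch(
    refine_candidate_interval(inst$lines, inst$map, inst$prior)$intervals,
    hifflux_inconsistency_error = function(e) NULL)
  want <- oracle_refine(inst$lines, inst$pos, inst$prior)
  if (is.null(got) || is.null(want)) return(is.null(got) && is.null(want))
  isTRUE(all.equal(got[, c("start_bp", "end_bp")], want,
                   check.attributes = FALSE))
}
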