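# Marker map carrying the six published marker positions that bound the
# successive fine-mapping intervals on chromosome 4.
published_map <- function() {
  marker_map(
    c("mk_left", "mk_117_l", "mk_final_l", "mk_final_r", "mk_117_r", "mk_right"),
    "4",
    c(7180000, 8211624, 8290453, 8298328, 8329176, 13079020))
}

# Segregation pattern consistent only with the final 7,875-bp interval:
# the first-screen segregating span, a second-screen segregating rHIF, and
# two non-segregating rHIFs that trim both flanks.
published_lines <- function() {
  data.frame(
    line_id = c("screen1_seg", "rHIF_seg", "rHIF_non_a", "rHIF_non_b"),
    start_bp = c(8211624, 8290453, 8298328, 7180000),
    end_bp = c(8329176, 8329176, 13079020, 8290453),
    verdict = c("segregating", "segregating", "non_segregating",
                "non_segregating"),
    stringsAsFactors = FALSE)
}

# small four-marker map used across breakpoint tests
four_marker_map <- function() {
  marker_map(paste0("m", 1:4), "4", c(1e6, 2e6, 3e6, 4e6))
}

# genotype table where exactly `n_rec` of `n_total` rows carry one in-region
# transition (A block then B block); the rest are uniform
engineered_screen <- function(n_total = 276, n_rec = 77, n_markers = 10) {
  map <- marker_map(sprintf("m%02d", 1:n_markers), "4",
                    round(seq(7180000, 13079020, length.out = n_markers)))
  calls <- matrix("A", n_total, n_markers)
  for (k in seq_len(n_rec)) {
    cut <- 1 + (k %% (n_markers - 1))
    calls[k, (cut + 1):n_markers] <- "B"
  }
  list(map = map, geno = genotype_table(sprintf("P%03d", 1:n_total), calls, map))
}
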