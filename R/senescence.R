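#' Senescent-leaf fraction
#'
#' Ratio of yellow rosette leaves to the total number of rosette leaves
#' counted at bolting (whole-leaf binary scoring).
#'
#' @param n_yellow count of yellow leaves
#' @param n_total_at_bolting total rosette leaf count at bolting (>= 1)
#' @return fraction in \[0, 1\]
#' @export
senescent_leaf_fraction <- function(n_yellow, n_total_at_bolting) {
  hf_assert(all(n_total_at_bolting >= 1), "total leaf count must be >= 1")
  hf_assert(all(n_yellow >= 0), "yellow leaf count must be >= 0")
  hf_assert(all(n_yellow <= n_total_at_bolting),
            "yellow leaves cannot exceed total leaves at bolting")
  n_yellow / n_total_at_bolting
}

#' Leaf-rank group
#'
#' Fixed rank windows used when pooling leaves for elemental analysis:
#' old leaves (OL) ranks 1-10, mature (ML) 11-20, young (YL) 21-30, new
#' (NL) 31 and above. Cauline leaves carry no rank.
#'
#' @param rank positive integer leaf rank(s), numbered old to young
#' @return factor with levels `OL`, `ML`, `YL`, `NL`
#' @examples
#' assign_leaf_group(c(1, 10, 11, 20, 21, 30, 31, 44))
#' @export
assign_leaf_group <- function(rank) {
  hf_assert(all(rank >= 1 & rank == round(rank)),
            "leaf rank must be a positive integer")
  lab <- c("OL", "ML", "YL", "NL")
  cut(rank, breaks = c(0, 10, 20, 30, Inf), labels = lab)
}

#' Detect the onset of chlorophyll decline
#'
#' The onset of leaf senescence is the first observation after the series
#' maximum at which the chlorophyll index has fallen by at least
#' `drop_threshold` of the maximum, sustained for `k_consecutive` successive
#' observations. Onsets before flower bud emergence mark sequential
#' senescence; onsets at or after it mark monocarpic senescence.
#'
#' @param das strictly increasing days after sowing (>= 3 observations)
#' @param chl chlorophyll index at each day
#' @param flower_bud_das day of flower bud emergence
#' @param drop_threshold required relative drop from the maximum (default 0.05)
#' @param k_consecutive observations that must sustain the drop (default 2)
#' @return list with `onset_das` (`NA` if no onset) and
#'   `phase` (`"sequential"`, `"monocarpic"` or `"none"`)
#' @export
detect_senescence_onset <- function(das, chl, flower_bud_das,
                                    drop_threshold = 0.05,
                                    k_consecutive = 2L) {
  hf_assert(length(das) == length(chl), "das and chl must have equal length")
  hf_assert(length(das) >= 3, "onset detection needs at least 3 observations")
  hf_assert(all(diff(das) > 0), "das must be strictly increasing")
  hf_assert(drop_threshold > 0, "drop_threshold must be > 0")
  hf_assert(k_consecutive >= 1, "k_consecutive must be >= 1")
  n <- length(chl)
  m_idx <- which.max(chl)
  thresh <- max(chl) * (1 - drop_threshold)
  below <- chl <= thresh
  onset <- NA_real_
  for (i in seq_len(n)) {
    if (i <= m_idx) next
    if (i + k_consecutive - 1L > n) break
    if (all(below[i:(i + k_consecutive - 1L)])) { onset <- das[i]; break }
  }
  if (is.na(onset)) return(list(onset_das = NA_real_, phase = "none"))
  list(onset_das = onset,
       phase = if (onset < flower_bud_das) "sequential" else "monocarpic")
}
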