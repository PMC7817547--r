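# 15N tracer bookkeeping. Internal conventions: masses in mg, enrichment E
# and allocation fractions as dimensionless fractions; percents (N%, atom%)
# appear only at the I/O boundary.

NATURAL_A_CONTROL <- 0.3660   # atom percent 15N of unlabeled plant material
DEFAULT_E_SOLUTION <- (10 - NATURAL_A_CONTROL) / 100  # 10 atom% labeling solution

REMOB_ORGANS <- c("rosette", "stem", "seeds")

#' 15N atom percent
#'
#' `A% = 100 * n15 / (n15 + n14)` from the two isotope signals.
#'
#' @param n15,n14 non-negative isotope signals (any common unit)
#' @return atom percent in \[0, 100\]
#' @examples
#' atom_percent(0.366, 99.634)  # natural abundance scale
#' @export
atom_percent <- function(n15, n14) {
  hf_assert(is.numeric(n15) && is.numeric(n14) && all(n15 >= 0) && all(n14 >= 0),
            "isotope signals must be non-negative numbers")
  tot <- n15 + n14
  hf_assert(all(tot > 0), "both isotope signals are zero")
  100 * n15 / tot
}

#' 15N enrichment above the unlabeled control
#'
#' `E = (A%_sample - A%_control) / 100`, a dimensionless atom fraction.
#' Samples below the control within `tol` atom percent are clipped to 0
#' (instrument noise at natural abundance); samples below by more than `tol`
#' are kept negative and flagged via the `"flagged"` attribute.
#'
#' @param a_sample,a_control atom percents in \[0, 100\]
#' @param tol clipping tolerance in atom percent (default 1e-4)
#' @return numeric enrichment fraction(s), attribute `flagged` (logical)
#' @export
enrichment <- function(a_sample, a_control = NATURAL_A_CONTROL, tol = 1e-4) {
  hf_assert(all(a_sample >= 0 & a_sample <= 100) &&
              all(a_control >= 0 & a_control <= 100),
            "atom percents must be in [0, 100]")
  d <- a_sample - a_control
  flagged <- d < -tol
  d[d < 0 & !flagged] <- 0
  e <- d / 100
  attr(e, "flagged") <- flagged
  e
}

#' Total and tracer nitrogen quantities of a sample
#'
#' `QtyN = DW * N% / 100` and `Qty15N = DW * E * N% / 100` (mg), with `N%`
#' a percent of dry weight and `E` the enrichment fraction.
#'
#' @param dw_mg dry weight in mg (> 0)
#' @param n_pct total N as percent of dry weight
#' @param e enrichment fraction (>= 0)
#' @return list with `qty_n_mg` and `qty_n15_mg`
#' @export
n_quantities <- function(dw_mg, n_pct, e) {
  hf_assert(all(dw_mg > 0), "dry weight must be positive")
  hf_assert(all(n_pct >= 0 & n_pct <= 100), "N percent must be in [0, 100]")
  hf_assert(all(e >= 0 & e <= 1), "enrichment fraction must be in [0, 1]")
  qty_n <- dw_mg * n_pct / 100
  list(qty_n_mg = qty_n, qty_n15_mg = qty_n * e)
}

#' Harvest index and N / 15N allocation fractions of one plant
#'
#' For the remobilization design the plant is partitioned into rosette, stem
#' and seeds (roots are not harvested). `HI = DW_seeds / sum(DW)`; the N and
#' 15N allocation of each organ is its share of the summed `QtyN` and
#' `Qty15N`; `NHI` and `NHI15` are the seed shares. When the summed tracer
#' (or N) is zero the corresponding fractions are undefined: they are
#' returned as `NA` with a flag, never as NaN.
#'
#' @param organs data.frame with one row per organ: columns `organ`,
#'   `dw_mg`, `qty_n_mg`, `qty_n15_mg`
#' @param require_remob require exactly the rosette/stem/seeds organ set
#' @return list with `hi`, `n_alloc`, `n15_alloc` (named vectors), `nhi`,
#'   `nhi15`, `flags` (character)
#' @export
partition_fractions <- function(organs, require_remob = TRUE) {
  hf_assert(all(c("organ", "dw_mg", "qty_n_mg", "qty_n15_mg") %in% names(organs)),
            "organs must have organ, dw_mg, qty_n_mg, qty_n15_mg")
  hf_assert(!anyDuplicated(organs$organ), "duplicated organ")
  if (require_remob) {
    hf_assert(setequal(organs$organ, REMOB_ORGANS),
              "remobilization partition requires exactly rosette, stem, seeds")
  }
  hf_assert(all(organs$dw_mg > 0), "dry weights must be positive")
  hf_assert(all(organs$qty_n15_mg >= 0), "tracer quantities must be >= 0")
  org <- organs$organ
  seed_organ <- if ("seeds" %in% org) "seeds"
                else if ("silique" %in% org) "silique" else NA_character_
  if (require_remob)
    hf_assert(!is.na(seed_organ), "no seed/silique organ present")

  flags <- character(0)
  hi <- if (is.na(seed_organ)) NA_real_
        else organs$dw_mg[org == seed_organ] / sum(organs$dw_mg)

  tot_n <- sum(organs$qty_n_mg)
  if (tot_n > 0) {
    n_alloc <- stats::setNames(organs$qty_n_mg / tot_n, org)
  } else {
    n_alloc <- stats::setNames(rep(NA_real_, length(org)), org)
    flags <- c(flags, "zero_total_n")
  }
  tot_15 <- sum(organs$qty_n15_mg)
  if (tot_15 > 0) {
    n15_alloc <- stats::setNames(organs$qty_n15_mg / tot_15, org)
  } else {
    n15_alloc <- stats::setNames(rep(NA_real_, length(org)), org)
    flags <- c(flags, "zero_total_tracer")
  }
  list(hi = hi,
       n_alloc = n_alloc, n15_alloc = n15_alloc,
       nhi = if (is.na(seed_organ)) NA_real_ else unname(n_alloc[seed_organ]),
       nhi15 = if (is.na(seed_organ)) NA_real_ else unname(n15_alloc[seed_organ]),
       flags = if (is.na(seed_organ)) c(flags, "no_seed_organ") else flags)
}

#' Nitrogen remobilization efficiency
#'
#' `NRE = NHI15 / HI`: the share of the pre-bolting tracer pulse recovered
#' in seeds, relative to the biomass share routed to seeds. Dimensionless;
#' values above 1 mean the tracer is routed to seeds more efficiently than
#' biomass.
#'
#' @param nhi15 seed share of the tracer (fraction)
#' @param hi harvest index (fraction, > 0)
#' @return NRE
#' @export
remobilization_efficiency <- function(nhi15, hi) {
  hf_assert(all(hi > 0), "HI must be > 0")
  nhi15 / hi
}

#' Nitrogen uptake efficiency over a 24-h labeling pulse
#'
#' `NUpE = (sum(Qty15N) / E_solution) / total DW`: total N absorbed during
#' the pulse (back-calculated from the tracer via the labeling-solution
#' enrichment) per unit plant biomass. Reported in mg N per g dry weight
#' per 24-h pulse; organs follow the shoot-based formula (root excluded
#' unless `include_root`).
#'
#' @param qty_n15_mg named vector of per-organ tracer quantities (mg)
#' @param e_solution labeling-solution enrichment as a fraction (> 0);
#'   default `(10 - 0.366) / 100` for a 10 atom% solution above natural
#'   background
#' @param dw_mg named vector of per-organ dry weights (mg), same organs
#' @param include_root include the root compartment in both sums
#' @return NUpE in mg N g^-1 DW per 24 h
#' @export
uptake_efficiency <- function(qty_n15_mg, dw_mg,
                              e_solution = DEFAULT_E_SOLUTION,
                              include_root = FALSE) {
  hf_assert(e_solution > 0, "E_solution must be > 0")
  hf_assert(all(dw_mg > 0), "dry weights must be positive")
  if (!include_root && !is.null(names(qty_n15_mg))) {
    keep <- names(qty_n15_mg) != "root"
    qty_n15_mg <- qty_n15_mg[keep]
    dw_mg <- dw_mg[keep]
  }
  (sum(qty_n15_mg) / e_solution) / (sum(dw_mg) / 1000)
}

#' Tracer translocation profile across organs
#'
#' Per-organ share of the total tracer pulse (root included), describing
#' where the newly absorbed N resides at harvest. Undefined (all `NA`,
#' flagged) when the plant carries no tracer.
#'
#' @param qty_n15_mg named vector of per-organ tracer quantities (mg),
#'   at least 2 organs
#' @return named vector of fractions summing to 1, attribute `flagged`
#' @export
translocation_profile <- function(qty_n15_mg) {
  hf_assert(length(qty_n15_mg) >= 2, "need at least 2 organs")
  hf_assert(all(qty_n15_mg >= 0), "tracer quantities must be >= 0")
  tot <- sum(qty_n15_mg)
  if (tot == 0) {
    out <- stats::setNames(rep(NA_real_, length(qty_n15_mg)), names(qty_n15_mg))
    attr(out, "flagged") <- "zero_total_tracer"
    return(out)
  }
  out <- qty_n15_mg / tot
  attr(out, "flagged") <- character(0)
  out
}

#' Per-plant flux summary from an organ-sample table
#'
#' Runs the full bookkeeping chain (atom percent in, enrichment, N
#' quantities, partition fractions, NRE and, for uptake experiments, NUpE)
#' on a table of organ samples. Rows with `experiment == "control"` are
#' unlabeled controls: their mean atom percent overrides `a_control`.
#' In post-flowering uptake experiments the silique plays the seed role and
#' is reported under the `seeds` columns.
#'
#' @param samples data.frame with columns `plant_id`, `genotype`,
#'   `experiment`, `organ`, `dw_mg`, `n_pct`, `a15n_pct`
#' @param experiment `"remobilization"`, `"uptake_vegetative"` or
#'   `"uptake_postflowering"`; default taken from the table when unique
#' @param a_control control atom percent; overridden by control rows
#' @param e_solution labeling-solution enrichment fraction (NUpE)
#' @param tol negative-enrichment clipping tolerance (atom percent)
#' @param include_root include roots in NUpE sums (default FALSE, following
#'   the shoot-based formula)
#' @return data.frame of class `flux_summary`, one row per plant: `hi`,
#'   `n_alloc_*`, `n15_alloc_*`, `nhi`, `nhi15`, `nre`, `nupe`, `flags`
#' @export
flux_summary <- function(samples,
                         experiment = NULL,
                         a_control = NATURAL_A_CONTROL,
                         e_solution = DEFAULT_E_SOLUTION,
                         tol = 1e-4,
                         include_root = FALSE) {
  req <- c("plant_id", "genotype", "experiment", "organ", "dw_mg",
           "n_pct", "a15n_pct")
  hf_assert(all(req %in% names(samples)),
            paste("samples must have columns:", paste(req, collapse = ", ")))
  ctrl <- samples[samples$experiment == "control", , drop = FALSE]
  if (nrow(ctrl) > 0) a_control <- mean(ctrl$a15n_pct)
  lab <- samples[samples$experiment != "control", , drop = FALSE]
  hf_assert(nrow(lab) > 0, "no labeled samples")
  if (is.null(experiment)) {
    ex <- unique(lab$experiment)
    hf_assert(length(ex) == 1,
              "several experiments present; supply `experiment`")
    experiment <- ex
  } else {
    lab <- lab[lab$experiment == experiment, , drop = FALSE]
    hf_assert(nrow(lab) > 0, sprintf("no samples for experiment '%s'", experiment))
  }
  hf_assert(experiment %in%
              c("remobilization", "uptake_vegetative", "uptake_postflowering"),
            "unknown experiment")
  dup <- duplicated(lab[, c("plant_id", "organ")])
  if (any(dup)) {
    hf_stop(sprintf("duplicate (plant, organ) pair: %s / %s",
                    lab$plant_id[dup][1], lab$organ[dup][1]))
  }
  # silique is the seed-role organ after flowering
  lab$organ[lab$organ == "silique"] <- "seeds"

  out <- lapply(split(lab, lab$plant_id), function(p) {
    e <- enrichment(p$a15n_pct, a_control, tol = tol)
    neg <- attr(e, "flagged")
    e_use <- pmax(as.numeric(e), 0)
    q <- n_quantities(p$dw_mg, p$n_pct, e_use)
    organs <- data.frame(organ = p$organ, dw_mg = p$dw_mg,
                         qty_n_mg = q$qty_n_mg, qty_n15_mg = q$qty_n15_mg,
                         stringsAsFactors = FALSE)
    shoot <- organs[organs$organ != "root", , drop = FALSE]
    pf <- partition_fractions(shoot,
                              require_remob = experiment == "remobilization")
    flags <- pf$flags
    if (any(neg)) flags <- c(flags, "negative_enrichment")
    nre <- if (is.na(pf$nhi15) || is.na(pf$hi)) NA_real_
           else remobilization_efficiency(pf$nhi15, pf$hi)
    nupe <- if (startsWith(experiment, "uptake")) {
      uptake_efficiency(stats::setNames(organs$qty_n15_mg, organs$organ),
                        stats::setNames(organs$dw_mg, organs$organ),
                        e_solution = e_solution, include_root = include_root)
    } else NA_real_
    row <- data.frame(plant_id = p$plant_id[1], genotype = p$genotype[1],
                      experiment = experiment, hi = pf$hi,
                      nhi = pf$nhi, nhi15 = pf$nhi15, nre = nre, nupe = nupe,
                      flags = paste(flags, collapse = ";"),
                      stringsAsFactors = FALSE)
    for (o in shoot$organ) {
      row[[paste0("n_alloc_", o)]] <- unname(pf$n_alloc[o])
      row[[paste0("n15_alloc_", o)]] <- unname(pf$n15_alloc[o])
    }
    row
  })
  common <- Reduce(union, lapply(out, names))
  out <- lapply(out, function(r) { r[setdiff(common, names(r))] <- NA; r[common] })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "a_control") <- a_control
  attr(res, "e_solution") <- e_solution
  class(res) <- c("flux_summary", "data.frame")
  res
}
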