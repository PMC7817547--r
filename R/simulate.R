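# Forward generators with known ground truth, emulating the two
# experimental designs: a selfed HIF progeny screen segregating over one
# residual heterozygous region (Haldane crossover model, no interference)
# and a pulse 15N labeling experiment with organ-level tracer partitioning
# constructed as the exact inverse of the analysis formulas at zero noise.

#' Evenly spaced marker map over a region
#'
#' @param n_markers number of markers (>= 2), including both region bounds
#' @param chrom chromosome label
#' @param start_bp,end_bp region bounds in bp; defaults are the 5.9-Mb
#'   residual heterozygous region used throughout the examples
#' @return a [marker_map()]
#' @export
sim_marker_map <- function(n_markers = 25, chrom = "4",
                           start_bp = 7180000, end_bp = 13079020) {
  hf_assert(n_markers >= 2, "need at least 2 markers")
  pos <- round(seq(start_bp, end_bp, length.out = n_markers))
  marker_map(sprintf("m%02d", seq_len(n_markers)), chrom, pos)
}

# Haldane recombination fraction for a distance of d Morgans
haldane_r <- function(d) (1 - exp(-2 * d)) / 2

#' Simulate selfed progeny genotypes over a heterozygous region
#'
#' Each progeny of a selfed heterozygous plant receives two independent
#' gametes. Along each gamete, a crossover occurs between adjacent loci with
#' the Haldane probability `r = (1 - exp(-2 d)) / 2`, `d` the inter-locus
#' distance in Morgans (`Mb * cM_per_Mb / 100`), independently across
#' intervals (no interference). Genotype calls combine the two gametes:
#' A+A -> `A`, B+B -> `B`, otherwise `H`.
#'
#' @param map a [marker_map()] (one chromosome)
#' @param n_progeny number of progeny plants
#' @param cm_per_mb genetic-to-physical rate in cM/Mb (default 3)
#' @param extra_loci optional bp positions of unmarked loci (e.g. the causal
#'   polymorphism) to track in the truth record but not in the genotype table
#' @param seed optional RNG seed
#' @return list with `genotypes` (a [genotype_table()]), `extra_genotypes`
#'   (data.frame `line_id`, `pos_bp`, `call` for each extra locus), and
#'   `truth` (list with per-gamete crossover indicators per interval and the
#'   full locus positions)
#' @export
simulate_progeny_genotypes <- function(map, n_progeny, cm_per_mb = 3,
                                       extra_loci = NULL, seed = NULL) {
  with_seed(seed, {
    sub <- map_chrom(map, NULL, NULL)
    hf_assert(all(diff(sub$pos_bp) > 0), "marker positions must increase")
    hf_assert(cm_per_mb >= 0, "cm_per_mb must be >= 0")
    pos <- sort(unique(c(sub$pos_bp, extra_loci)))
    is_marker <- pos %in% sub$pos_bp
    n_loci <- length(pos)
    d <- diff(pos) / 1e6 * cm_per_mb / 100    # Morgans
    r <- haldane_r(d)

    n_gam <- 2L * n_progeny
    # gamete = starting allele, then cumulative crossover switches (mod 2)
    start <- sample(0:1, n_gam, replace = TRUE)
    xo <- matrix(stats::rbinom(n_gam * (n_loci - 1L), 1L, rep(r, each = n_gam)),
                 nrow = n_gam)
    cs <- if (ncol(xo) == 1L) xo else t(apply(xo, 1L, cumsum))
    state <- (start + cbind(0L, cs)) %% 2L
    g1 <- state[seq(1L, n_gam, by = 2L), , drop = FALSE]
    g2 <- state[seq(2L, n_gam, by = 2L), , drop = FALSE]
    dosage <- g1 + g2                          # copies of the B allele
    calls_all <- matrix(c("A", "H", "B")[dosage + 1L], nrow = n_progeny)

    ids <- sprintf("P%04d", seq_len(n_progeny))
    geno <- genotype_table(ids, calls_all[, is_marker, drop = FALSE], sub)
    extra <- NULL
    if (!is.null(extra_loci)) {
      idx <- match(extra_loci, pos)
      extra <- data.frame(
        line_id = rep(ids, times = length(extra_loci)),
        pos_bp = rep(extra_loci, each = n_progeny),
        call = as.vector(calls_all[, idx, drop = FALSE]),
        dosage_b = as.vector(dosage[, idx, drop = FALSE]),
        stringsAsFactors = FALSE)
    }
    list(genotypes = geno,
         extra_genotypes = extra,
         truth = list(crossovers = xo, loci_bp = pos, r = r,
                      cm_per_mb = cm_per_mb, seed = seed))
  })
}

#' Simulate an additive biallelic QTL phenotype
#'
#' `value = baseline + effect_size * dosage_B / 2 + N(0, noise_sd)`: the B
#' allele increases the trait (e.g. the senescent-leaf fraction) additively.
#'
#' @param dosage_b copies of the B allele (0, 1 or 2) per individual
#' @param effect_size difference between the two homozygote classes
#' @param noise_sd Gaussian noise standard deviation
#' @param baseline trait value of the A homozygote
#' @param seed optional RNG seed
#' @return numeric phenotype vector
#' @export
simulate_phenotypes <- function(dosage_b, effect_size = 0.2, noise_sd = 0.05,
                                baseline = 0.2, seed = NULL) {
  with_seed(seed, {
    hf_assert(all(dosage_b %in% 0:2), "dosage must be 0, 1 or 2")
    baseline + effect_size * dosage_b / 2 +
      stats::rnorm(length(dosage_b), 0, noise_sd)
  })
}

#' Run one simulated fine-mapping campaign
#'
#' Full pipeline on simulated data: screen `n_progeny` selfed progeny of a
#' heterozygous plant, detect recombinants, run a fixed-progeny segregation
#' test on every recombinant (two fixed classes of `n_rep` plants each,
#' phenotypes from the additive QTL model), and refine the candidate
#' interval. Segregating lines contribute their wide heterozygous span
#' (flanking informative homozygous markers), non-segregating lines their
#' narrow span (H-call markers), whose open interior is subtracted.
#'
#' A line is declared segregating when the Welch test gives p < `alpha`
#' *and* the progeny-class difference is at least `min_effect`: in a
#' campaign testing tens of lines, a p-value alone would mislabel about
#' `alpha` of the truly non-segregating lines and wrongly shrink the
#' interval, so the verdict additionally requires a difference commensurate
#' with the known parental HIF contrast (default half the allelic effect;
#' set 0 to disable).
#'
#' @param map marker map (default 25 markers over the 5.9-Mb region)
#' @param causal_pos_bp true causal position (inside the region)
#' @param n_progeny progeny screened (default 276)
#' @param cm_per_mb crossover rate (default 3)
#' @param effect_size,noise_sd,baseline QTL model ([simulate_phenotypes()])
#' @param n_rep phenotyped plants per fixed class (default 12: three fixed
#'   plants per allele, four replicates each)
#' @param alpha per-line significance level
#' @param min_effect minimum absolute class difference for a segregating
#'   verdict (default `effect_size / 2`)
#' @param seed optional RNG seed
#' @return list with `candidate` ([refine_candidate_interval()] result),
#'   `covered` (is the causal position inside a returned interval),
#'   `recombinants`, `calls` (per-line het spans + verdicts), `causal_pos_bp`
#' @export
run_finemap_campaign <- function(map = sim_marker_map(),
                                 causal_pos_bp = 8294000,
                                 n_progeny = 276, cm_per_mb = 3,
                                 effect_size = 0.2, noise_sd = 0.05,
                                 baseline = 0.2, n_rep = 12,
                                 alpha = 0.05, min_effect = effect_size / 2,
                                 seed = NULL) {
  with_seed(seed, {
    sub <- map_chrom(map, NULL, NULL)
    region <- range(sub$pos_bp)
    hf_assert(causal_pos_bp > region[1] && causal_pos_bp < region[2],
              "causal position must lie inside the map span")
    sim <- simulate_progeny_genotypes(map, n_progeny, cm_per_mb,
                                      extra_loci = causal_pos_bp)
    rec <- detect_recombinants(sim$genotypes, map, region = region)

    calls <- data.frame(line_id = character(0), start_bp = numeric(0),
                        end_bp = numeric(0), verdict = character(0),
                        p_value = numeric(0), stringsAsFactors = FALSE)
    for (line in rec) {
      cv <- line_calls(sim$genotypes, line, sub)
      if (!any(cv == "H")) next       # recombined but fixed: nothing to test
      causal_call <- sim$extra_genotypes$call[
        sim$extra_genotypes$line_id == line]
      # fixed-progeny classes are selected by genotype at the visible het
      # MARKERS: the causal alleles co-fix with the markers only when the
      # causal locus lies within the marker-visible het span; a het segment
      # hidden between homozygous markers keeps segregating inside both
      # classes (random dosage), and a homozygous causal locus is identical
      # in both classes
      vis <- het_span(cv, map, flank = "informative")
      causal_visible <- !is.null(vis) &&
        vis[1] <= causal_pos_bp && causal_pos_bp <= vis[2]
      if (causal_call == "H" && causal_visible) {
        dos_a <- rep(0L, n_rep); dos_b <- rep(2L, n_rep)
      } else if (causal_call == "H") {
        dos_a <- sample(0:2, n_rep, replace = TRUE, prob = c(1, 2, 1) / 4)
        dos_b <- sample(0:2, n_rep, replace = TRUE, prob = c(1, 2, 1) / 4)
      } else {
        dos_a <- dos_b <- rep(if (causal_call == "A") 0L else 2L, n_rep)
      }
      pheno_a <- simulate_phenotypes(dos_a, effect_size, noise_sd, baseline)
      pheno_b <- simulate_phenotypes(dos_b, effect_size, noise_sd, baseline)
      tst <- progeny_test(pheno_a, pheno_b, alpha = alpha, line_id = line)
      verdict <- tst$verdict
      if (verdict == "segregating" &&
          abs(tst$mean_a - tst$mean_b) < min_effect)
        verdict <- "non_segregating"
      if (verdict == "segregating") {
        # causal locus is somewhere in this line's het region: its wide span
        # (flanking informative homozygous markers) is a sound superset
        span <- het_span(cv, map, flank = "informative")
        add <- data.frame(start_bp = span[1], end_bp = span[2])
      } else {
        # exclude the open interior of each het block separately; the
        # homozygous gap of a double recombinant stays a valid candidate
        add <- het_blocks(cv, map)
      }
      calls <- rbind(calls, data.frame(
        line_id = line, start_bp = add$start_bp, end_bp = add$end_bp,
        verdict = verdict, p_value = tst$p_value, stringsAsFactors = FALSE))
    }
    hf_assert(nrow(calls) > 0, "no testable recombinant in this campaign")
    # contradictory calls (e.g. a double crossover hugging the causal locus
    # plus an unlucky verdict) leave no surviving region: report the
    # conflict as a failed campaign rather than aborting
    cand <- tryCatch(refine_candidate_interval(calls, map, prior = region),
                     hifflux_inconsistency_error = function(e) e)
    if (inherits(cand, "condition")) {
      return(list(candidate = NULL, covered = FALSE, recombinants = rec,
                  calls = calls, causal_pos_bp = causal_pos_bp,
                  conflict = conditionMessage(cand)))
    }
    covered <- any(cand$intervals$start_bp <= causal_pos_bp &
                     cand$intervals$end_bp >= causal_pos_bp)
    list(candidate = cand, covered = covered, recombinants = rec,
         calls = calls, causal_pos_bp = causal_pos_bp, conflict = NULL)
  })
}

# mean-preserving lognormal multiplier with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Dirichlet sample around mean shares mu with precision kappa (kappa = Inf
# or 0 variability -> exact means)
rdirichlet1 <- function(mu, kappa) {
  if (!is.finite(kappa)) return(mu)
  g <- stats::rgamma(length(mu), shape = kappa * mu)
  g / sum(g)
}

#' Simulate a 15N labeling dataset with known flux truth
#'
#' Forward model of a pulse-labeling experiment for one genotype: organ dry
#' weights are lognormal around the genotype means, the absorbed tracer is
#' split across organs by Dirichlet-distributed shares around the true
#' shares, and each organ's atom percent is back-computed from its tracer
#' quantity so that the analysis formulas are exact inverses at zero noise.
#' Multiplicative measurement noise is then applied to dry weight and N
#' percent (additive on atom percent).
#'
#' @param n_plants plants to simulate
#' @param genotype genotype label
#' @param experiment `"remobilization"` (rosette/stem/seeds),
#'   `"uptake_vegetative"` (root/rosette) or `"uptake_postflowering"`
#'   (root/rosette/stem/silique)
#' @param organ_dw_mg named true mean dry weights (mg); defaults give
#'   HI = 0.25 for the remobilization set
#' @param n_pct named true N percents per organ
#' @param tracer_shares named true tracer shares (sum to 1); remobilization
#'   default routes half the pulse to seeds
#' @param tracer_total_mg true tracer mass absorbed per plant (mg 15N excess)
#' @param bio_cv biological CV of organ dry weights (lognormal)
#' @param meas_cv multiplicative measurement CV on dry weight and N percent
#' @param a_sd additive Gaussian sd on atom percent (atom %)
#' @param share_precision Dirichlet precision of the per-plant tracer shares
#' @param a_control unlabeled atom percent (atom %)
#' @param e_solution labeling-solution enrichment fraction (truth for NUpE)
#' @param n_controls unlabeled control samples appended to the table
#' @param seed optional RNG seed
#' @return list with `samples` (organ-sample data.frame as read by
#'   [flux_summary()]) and `truth` (per-plant data.frame of true HI, organ
#'   shares, NHI15, NRE, NUpE, plus the generator parameters as attributes)
#' @export
simulate_labeling_dataset <- function(n_plants = 18,
                                      genotype = "HIF-Col",
                                      experiment = "remobilization",
                                      organ_dw_mg = NULL,
                                      n_pct = NULL,
                                      tracer_shares = NULL,
                                      tracer_total_mg = 0.02,
                                      bio_cv = 0.1,
                                      meas_cv = 0.1,
                                      a_sd = 0,
                                      share_precision = 200,
                                      a_control = NATURAL_A_CONTROL,
                                      e_solution = DEFAULT_E_SOLUTION,
                                      n_controls = 3,
                                      seed = NULL) {
  defaults <- switch(
    experiment,
    remobilization = list(
      dw = c(rosette = 60, stem = 15, seeds = 25),
      n = c(rosette = 2, stem = 1.5, seeds = 4.5),
      sh = c(rosette = 0.3, stem = 0.2, seeds = 0.5)),
    uptake_vegetative = list(
      dw = c(root = 30, rosette = 90),
      n = c(root = 2.5, rosette = 4.5),
      sh = c(root = 0.45, rosette = 0.55)),
    uptake_postflowering = list(
      dw = c(root = 35, rosette = 70, stem = 60, silique = 45),
      n = c(root = 2, rosette = 3, stem = 1.5, silique = 3.5),
      sh = c(root = 0.25, rosette = 0.2, stem = 0.15, silique = 0.4)),
    hf_stop(sprintf("unknown experiment '%s'", experiment))
  )
  if (is.null(organ_dw_mg)) organ_dw_mg <- defaults$dw
  if (is.null(n_pct)) n_pct <- defaults$n
  if (is.null(tracer_shares)) tracer_shares <- defaults$sh
  organs <- names(organ_dw_mg)
  hf_assert(setequal(organs, names(n_pct)) &&
              setequal(organs, names(tracer_shares)),
            "organ names must agree across organ_dw_mg, n_pct, tracer_shares")
  hf_assert(abs(sum(tracer_shares) - 1) < 1e-9, "tracer shares must sum to 1")
  hf_assert(bio_cv >= 0 && meas_cv >= 0 && a_sd >= 0, "CVs must be >= 0")

  with_seed(seed, {
    n_org <- length(organs)
    rows <- vector("list", n_plants)
    truth <- vector("list", n_plants)
    for (i in seq_len(n_plants)) {
      pid <- sprintf("%s_%s_p%03d", genotype, experiment, i)
      dw_true <- organ_dw_mg * rlnorm_cv(n_org, bio_cv)
      shares <- rdirichlet1(tracer_shares[organs],
                            if (bio_cv == 0) Inf else share_precision)
      q15_true <- tracer_total_mg * shares
      qn_true <- dw_true * n_pct[organs] / 100
      hf_assert(all(q15_true <= qn_true),
                "tracer quantity exceeds total N; lower tracer_total_mg")
      e_true <- q15_true / qn_true
      a_true <- a_control + 100 * e_true

      dw_m <- dw_true * rlnorm_cv(n_org, meas_cv)
      n_m <- n_pct[organs] * rlnorm_cv(n_org, meas_cv)
      a_m <- a_true + stats::rnorm(n_org, 0, a_sd)

      rows[[i]] <- data.frame(
        plant_id = pid, genotype = genotype, experiment = experiment,
        organ = organs, dw_mg = unname(dw_m), n_pct = unname(n_m),
        a15n_pct = unname(a_m), stringsAsFactors = FALSE)

      shoot <- organs[organs != "root"]
      seed_org <- intersect(c("seeds", "silique"), organs)
      hi <- if (length(seed_org))
        unname(dw_true[seed_org] / sum(dw_true[shoot])) else NA_real_
      nhi15 <- if (length(seed_org))
        unname(q15_true[seed_org] / sum(q15_true[shoot])) else NA_real_
      truth[[i]] <- data.frame(
        plant_id = pid, genotype = genotype, experiment = experiment,
        hi = hi, nhi15 = nhi15,
        nre = if (!is.na(hi) && hi > 0) nhi15 / hi else NA_real_,
        nupe = (sum(q15_true[shoot]) / e_solution) / (sum(dw_true[shoot]) / 1000),
        tracer_total_mg = tracer_total_mg, stringsAsFactors = FALSE)
      for (o in organs) truth[[i]][[paste0("share_", o)]] <- unname(shares[o])
    }
    samples <- do.call(rbind, rows)
    if (n_controls > 0) {
      ctrl <- data.frame(
        plant_id = sprintf("control_p%03d", seq_len(n_controls)),
        genotype = genotype, experiment = "control",
        organ = "rosette",
        dw_mg = unname(organ_dw_mg[[1]]) * rlnorm_cv(n_controls, meas_cv),
        n_pct = unname(n_pct[[1]]) * rlnorm_cv(n_controls, meas_cv),
        a15n_pct = a_control + stats::rnorm(n_controls, 0, a_sd),
        stringsAsFactors = FALSE)
      samples <- rbind(samples, ctrl)
    }
    truth <- do.call(rbind, truth)
    rownames(samples) <- rownames(truth) <- NULL
    attr(truth, "a_control") <- a_control
    attr(truth, "e_solution") <- e_solution
    attr(truth, "tracer_shares") <- tracer_shares
    list(samples = samples, truth = truth)
  })
}

#' Simulate chlorophyll kinetics with a programmed decline onset
#'
#' Piecewise curve per leaf rank: logistic rise toward a rank-dependent
#' plateau, then linear decline starting at a rank- and genotype-dependent
#' onset day, with additive Gaussian noise. The reported truth onset is the
#' first sampling day at or after the programmed decline start, i.e. the
#' first observation that shows the drop — the quantity
#' [detect_senescence_onset()] estimates.
#'
#' @param n_plants plants per genotype
#' @param leaf_ranks integer leaf ranks to simulate per plant
#' @param genotype_shift onset shift in days (e.g. -8 for an early-senescing
#'   genotype)
#' @param onset_base onset day of rank 1 for the reference genotype
#' @param onset_per_rank onset delay per leaf rank (days)
#' @param flower_bud_das flower bud emergence day (default 52)
#' @param sample_days observation grid (days after sowing)
#' @param plateau_base,plateau_per_rank chlorophyll plateau (index units)
#' @param rise_rate logistic rise rate (per day)
#' @param decline_rate linear decline per day, as a fraction of the plateau
#' @param noise_sd additive noise as a fraction of the plateau
#' @param genotype genotype label
#' @param seed optional RNG seed
#' @return list with `series` (data.frame `plant_id`, `genotype`,
#'   `leaf_rank`, `das`, `chl_index`, `flower_bud_das`) and `truth`
#'   (data.frame with programmed `onset_das` per plant x rank)
#' @export
simulate_chlorophyll_kinetics <- function(n_plants = 4,
                                          leaf_ranks = c(5, 10, 15, 20),
                                          genotype_shift = 0,
                                          onset_base = 38,
                                          onset_per_rank = 0.8,
                                          flower_bud_das = 52,
                                          sample_days = seq(20, 88, by = 4),
                                          plateau_base = 20,
                                          plateau_per_rank = 0.5,
                                          rise_rate = 0.25,
                                          decline_rate = 0.03,
                                          noise_sd = 0,
                                          genotype = "ref",
                                          seed = NULL) {
  hf_assert(length(sample_days) >= 3 && all(diff(sample_days) > 0),
            "sample_days must be >= 3 increasing days")
  dt <- stats::median(diff(sample_days))
  with_seed(seed, {
    rows <- list(); truth <- list()
    for (p in seq_len(n_plants)) {
      pid <- sprintf("%s_p%02d", genotype, p)
      for (rk in leaf_ranks) {
        plateau <- plateau_base + plateau_per_rank * rk
        onset <- onset_base + onset_per_rank * rk + genotype_shift
        t_mid <- onset - 20
        rise <- plateau / (1 + exp(-rise_rate * (sample_days - t_mid)))
        v_onset <- plateau / (1 + exp(-rise_rate * (onset - t_mid)))
        decl <- v_onset * (1 - decline_rate * (sample_days - onset + dt))
        v <- ifelse(sample_days < onset, rise, pmax(decl, 0))
        v <- v + stats::rnorm(length(v), 0, noise_sd * plateau)
        rows[[length(rows) + 1L]] <- data.frame(
          plant_id = pid, genotype = genotype, leaf_rank = rk,
          das = sample_days, chl_index = v, flower_bud_das = flower_bud_das,
          stringsAsFactors = FALSE)
        grid_onset <- sample_days[sample_days >= onset]
        truth[[length(truth) + 1L]] <- data.frame(
          plant_id = pid, genotype = genotype, leaf_rank = rk,
          onset_param = onset,
          onset_das = if (length(grid_onset)) grid_onset[1] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    list(series = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
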