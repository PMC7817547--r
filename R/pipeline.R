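#' Run an analysis pipeline stage
#'
#' Dispatches the four pipeline commands on file inputs and writes results
#' plus a reproducibility manifest (inputs, parameters, seed, package
#' version, output checksums) into `out_dir`.
#'
#' Commands:
#' \describe{
#'   \item{finemap}{`map`, `genotypes`, `phenotypes` (fixed-progeny CSV),
#'     `region` string; detects recombinants, tests each line, refines the
#'     candidate interval; writes `calls.csv` and `interval.json`, logging
#'     every narrowing step.}
#'   \item{flux}{`samples` organ CSV; writes per-plant `flux.csv` and, with
#'     more than one genotype, `contrast.txt`.}
#'   \item{senescence}{`scores` and/or `chlorophyll` CSVs; writes
#'     `scores.csv` / `onset.csv`.}
#'   \item{simulate}{`what` = campaign | labeling | chlorophyll; writes the
#'     generated CSVs together with the ground truth.}
#' }
#'
#' @param cfg named list (or path to a YAML file) with `command`, input
#'   paths, parameters, `out_dir`, and optional `seed`
#' @return list of written paths (including `manifest`), invisibly
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  hf_assert(is.list(cfg) && !is.null(cfg$command), "cfg must name a command")
  hf_assert(!is.null(cfg$out_dir), "cfg must name out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  inputs <- list()
  outputs <- character(0)
  put <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write_table_csv(x, p)
    outputs <<- c(outputs, p)
    p
  }

  switch(
    cfg$command,
    finemap = {
      map <- read_marker_map(cfg$map)
      geno <- read_genotype_table(cfg$genotypes, map)
      pheno <- read_progeny_phenotypes(cfg$phenotypes)
      reg <- parse_region(cfg$region)
      alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
      min_effect <- if (is.null(cfg$min_effect)) 0 else cfg$min_effect
      max_missing <- if (is.null(cfg$max_missing)) 0.5 else cfg$max_missing
      inputs <- list(map = cfg$map, genotypes = cfg$genotypes,
                     phenotypes = cfg$phenotypes)
      sub <- map_chrom(map, reg$chrom)
      region <- c(reg$start_bp, reg$end_bp)
      rec <- detect_recombinants(geno, map, region, chrom = reg$chrom)
      message(sprintf("finemap: %d lines screened, %d recombinants in %s",
                      nrow(geno), length(rec), cfg$region))
      calls <- NULL
      for (line in intersect(rec, unique(pheno$line_id))) {
        cv <- line_calls(geno, line, sub)
        if (missing_fraction(cv[sub$pos_bp >= region[1] &
                                  sub$pos_bp <= region[2]]) > max_missing) {
          message(sprintf("finemap: %s excluded (>%.0f%% missing calls)",
                          line, 100 * max_missing))
          next
        }
        ph <- pheno[pheno$line_id == line, ]
        tst <- progeny_test(ph$value[ph$allele == "A"],
                            ph$value[ph$allele == "B"],
                            alpha = alpha, line_id = line)
        verdict <- tst$verdict
        if (verdict == "segregating" &&
            abs(tst$mean_a - tst$mean_b) < min_effect)
          verdict <- "non_segregating"
        if (verdict == "segregating") {
          span <- het_span(cv, map, chrom = reg$chrom, region = region,
                           flank = "informative")
          if (is.null(span)) next
          add <- data.frame(start_bp = span[1], end_bp = span[2])
        } else {
          add <- het_blocks(cv, map, chrom = reg$chrom, region = region)
          if (nrow(add) == 0) next
        }
        calls <- rbind(calls, data.frame(
          line_id = line, start_bp = add$start_bp, end_bp = add$end_bp,
          verdict = verdict, p_value = tst$p_value,
          method = tst$method, stringsAsFactors = FALSE))
      }
      hf_assert(!is.null(calls), "no testable recombinant line")
      prior_width <- region[2] - region[1]
      cand <- refine_candidate_interval(calls, map, prior = region,
                                        chrom = reg$chrom)
      message(sprintf(
        "finemap: prior width %s bp -> candidate width %s bp (%d lines: %s)",
        format(prior_width, big.mark = ","),
        format(sum(cand$intervals$width_bp), big.mark = ","),
        nrow(calls), paste(calls$line_id, collapse = ", ")))
      put(calls, "calls.csv")
      ip <- file.path(cfg$out_dir, "interval.json")
      jsonlite::write_json(list(
        chrom = cand$chrom, intervals = cand$intervals,
        conflicts = cand$conflicts, n_lines = cand$n_lines),
        ip, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, ip)
    },
    flux = {
      samples <- read_organ_samples(cfg$samples)
      inputs <- list(samples = cfg$samples)
      fs <- flux_summary(
        samples,
        experiment = cfg$experiment,
        a_control = if (is.null(cfg$a_control)) NATURAL_A_CONTROL else cfg$a_control,
        e_solution = if (is.null(cfg$e_solution)) DEFAULT_E_SOLUTION else cfg$e_solution)
      put(as.data.frame(fs), "flux.csv")
      if (length(unique(fs$genotype)) > 1) {
        ct <- genotype_contrast(as.data.frame(fs), response = "nre")
        cp <- file.path(cfg$out_dir, "contrast.txt")
        utils::capture.output(print(ct), file = cp)
        outputs <- c(outputs, cp)
      }
    },
    senescence = {
      if (!is.null(cfg$scores)) {
        sc <- read_senescence_scores(cfg$scores)
        inputs$scores <- cfg$scores
        put(sc, "scores.csv")
      }
      if (!is.null(cfg$chlorophyll)) {
        ch <- read_chlorophyll_series(cfg$chlorophyll)
        inputs$chlorophyll <- cfg$chlorophyll
        thr <- if (is.null(cfg$drop_threshold)) 0.05 else cfg$drop_threshold
        k <- if (is.null(cfg$k_consecutive)) 2L else cfg$k_consecutive
        key <- interaction(ch$plant_id, ch$leaf_rank, drop = TRUE)
        onset <- do.call(rbind, lapply(split(ch, key), function(s) {
          s <- s[order(s$das), ]
          o <- detect_senescence_onset(s$das, s$chl_index,
                                       s$flower_bud_das[1], thr, k)
          data.frame(plant_id = s$plant_id[1], leaf_rank = s$leaf_rank[1],
                     onset_das = o$onset_das, phase = o$phase,
                     flower_bud_das = s$flower_bud_das[1],
                     stringsAsFactors = FALSE)
        }))
        put(onset, "onset.csv")
      }
      hf_assert(length(inputs) > 0, "senescence needs scores and/or chlorophyll")
    },
    simulate = {
      what <- cfg$what
      hf_assert(!is.null(what), "simulate needs `what`")
      if (what == "labeling") {
        sim <- simulate_labeling_dataset(
          n_plants = if (is.null(cfg$n_plants)) 18 else cfg$n_plants,
          genotype = if (is.null(cfg$genotype)) "HIF-Col" else cfg$genotype,
          experiment = if (is.null(cfg$experiment)) "remobilization" else cfg$experiment,
          meas_cv = if (is.null(cfg$meas_cv)) 0.1 else cfg$meas_cv,
          bio_cv = if (is.null(cfg$bio_cv)) 0.1 else cfg$bio_cv,
          seed = seed)
        put(sim$samples, "samples.csv")
        put(sim$truth, "truth.csv")
      } else if (what == "campaign") {
        camp <- run_finemap_campaign(seed = seed)
        put(camp$calls, "calls.csv")
        put(camp$candidate$intervals, "interval.csv")
        put(data.frame(causal_pos_bp = camp$causal_pos_bp,
                       covered = camp$covered), "truth.csv")
      } else if (what == "chlorophyll") {
        sim <- simulate_chlorophyll_kinetics(
          noise_sd = if (is.null(cfg$noise_sd)) 0.02 else cfg$noise_sd,
          seed = seed)
        put(sim$series, "chlorophyll.csv")
        put(sim$truth, "truth.csv")
      } else hf_stop(sprintf("unknown simulate target '%s'", what))
    },
    hf_stop(sprintf("unknown command '%s'", cfg$command))
  )

  manifest <- list(
    command = cfg$command,
    parameters = cfg[setdiff(names(cfg), c("command", "out_dir"))],
    seed = seed,
    package = "hifflux",
    version = as.character(utils::packageVersion("hifflux")),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(outputs = outputs, manifest = mp))
}
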