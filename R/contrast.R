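# Genotype contrasts on per-plant flux summaries: two-way fixed-effects
# model (genotype + experiment batch), Tukey HSD with a compact letter
# display, least-square means via emmeans, and unpooled pairwise t tests.

# Insert-and-absorb compact letter display from a logical significance
# matrix over group pairs. Groups sharing a letter are not significantly
# different. `means` orders the letters (highest mean gets "a").
cld_letters <- function(groups, sig, means) {
  stopifnot(is.matrix(sig), nrow(sig) == length(groups))
  cols <- list(seq_along(groups))          # start: one letter for all
  pr <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    nxt <- list()
    for (col in cols) {
      if (i %in% col && j %in% col)
        nxt <- c(nxt, list(setdiff(col, i)), list(setdiff(col, j)))
      else nxt <- c(nxt, list(col))
    }
    nxt <- nxt[lengths(nxt) > 0]
    # absorb: drop columns contained in another (later of equal duplicates)
    drop <- rep(FALSE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a == b || drop[a] || drop[b]) next
      if (all(nxt[[a]] %in% nxt[[b]]) &&
          (length(nxt[[a]]) < length(nxt[[b]]) || a > b))
        drop[a] <- TRUE
    }
    cols <- nxt[!drop]
  }
  # order columns by the best (highest) mean they contain
  best <- vapply(cols, function(col) max(means[col]), numeric(1))
  cols <- cols[order(-best)]
  lab <- vapply(seq_along(groups), function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(lab, groups)
}

#' Genotype contrasts with batch adjustment
#'
#' Fits `value ~ experiment + genotype` (or `value ~ genotype` with a single
#' experiment), and reports the ANOVA table, Tukey HSD comparisons with a
#' compact letter display, least-square means (genotype means adjusted for
#' experiment batch, via \pkg{emmeans}), and unpooled pairwise Welch t
#' p-values.
#'
#' @param data data.frame with the response and grouping columns
#' @param response name of the numeric response column (default `"value"`)
#' @param genotype name of the genotype column
#' @param experiment name of the experiment/batch column (optional; ignored
#'   when absent or constant)
#' @param alpha significance level for the letter display
#' @return object of class `genotype_contrast`: list with `anova`,
#'   `lsmeans` (data.frame with letters), `tukey`, `pairwise_p`, `model`
#' @export
genotype_contrast <- function(data, response = "value", genotype = "genotype",
                              experiment = "experiment", alpha = 0.05) {
  hf_assert(response %in% names(data), sprintf("no column '%s'", response))
  hf_assert(genotype %in% names(data), sprintf("no column '%s'", genotype))
  d <- data.frame(value = as.numeric(data[[response]]),
                  genotype = factor(data[[genotype]]))
  has_batch <- experiment %in% names(data) &&
    length(unique(data[[experiment]])) > 1
  if (has_batch) d$experiment <- factor(data[[experiment]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  ng <- nlevels(droplevels(d$genotype))
  hf_assert(ng >= 2 || has_batch,
            "singular design: one genotype in one experiment")
  hf_assert(ng >= 2, "need at least 2 genotypes to contrast")
  hf_assert(all(table(d$genotype) >= 2), "each genotype needs >= 2 replicates")

  form <- if (has_batch) value ~ experiment + genotype else value ~ genotype
  fit <- stats::aov(form, data = d)
  anova_tab <- stats::anova(fit)

  tk <- stats::TukeyHSD(fit, which = "genotype")$genotype
  gl <- levels(d$genotype)
  sig <- matrix(FALSE, ng, ng, dimnames = list(gl, gl))
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (k in seq_along(cmp)) {
    i <- cmp[[k]][1]; j <- cmp[[k]][2]
    s <- tk[k, "p adj"] < alpha
    sig[i, j] <- s; sig[j, i] <- s
  }

  em <- emmeans::emmeans(fit, "genotype")
  ems <- as.data.frame(em)
  ems <- ems[match(gl, as.character(ems$genotype)), , drop = FALSE]
  letter <- cld_letters(gl, sig, means = ems$emmean)
  lsm <- data.frame(genotype = gl, lsmean = ems$emmean, se = ems$SE,
                    letters = unname(letter[gl]), stringsAsFactors = FALSE)

  # unpooled pairwise Welch tests; undefined (constant data) pairs are NA
  pw <- matrix(NA_real_, ng - 1, ng - 1,
               dimnames = list(gl[-1], gl[-ng]))
  for (i in 2:ng) for (j in 1:(i - 1)) {
    pw[gl[i], gl[j]] <- tryCatch(
      stats::t.test(d$value[d$genotype == gl[i]],
                    d$value[d$genotype == gl[j]])$p.value,
      error = function(e) NA_real_)
  }

  out <- list(anova = anova_tab, lsmeans = lsm,
              tukey = as.data.frame(tk), pairwise_p = pw,
              alpha = alpha, model = fit)
  class(out) <- "genotype_contrast"
  out
}

#' @export
print.genotype_contrast <- function(x, ...) {
  cat("Genotype contrast (ANOVA + Tukey HSD, least-square means)\n\n")
  print(x$anova)
  cat("\nLeast-square means:\n")
  print(x$lsmeans, row.names = FALSE)
  invisible(x)
}
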