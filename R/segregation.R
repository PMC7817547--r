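#' Fixed-progeny / progeny segregation test
#'
#' Welch two-sample t test between the phenotypes of progeny fixed for the
#' two parental alleles at a line's residual heterozygous interval. The
#' verdict is `"segregating"` when p < alpha, `"non_segregating"` otherwise,
#' and `"inconclusive"` when either group has fewer than 2 values (no test
#' possible). Degenerate zero-variance groups are resolved by their means
#' (identical means: p = 1; different means: p = 0).
#'
#' @param group_a,group_b numeric phenotype values of the two fixed classes
#' @param alpha significance level in (0, 1); default 0.05
#' @param method experimental design label, `"fixed_progeny"` or `"progeny"`
#' @param line_id optional id recorded in the call
#' @return object of class `segregation_call`: list with `line_id`,
#'   `verdict`, `p_value`, `alpha`, `method`, `mean_a`, `mean_b`, `n_a`, `n_b`
#' @examples
#' progeny_test(c(30, 35, 40), c(5, 8, 11))
#' @export
progeny_test <- function(group_a, group_b, alpha = 0.05,
                         method = c("fixed_progeny", "progeny"),
                         line_id = NA_character_) {
  method <- match.arg(method)
  hf_assert(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
            "alpha must be in (0, 1)")
  hf_assert(is.numeric(group_a) && is.numeric(group_b),
            "phenotype groups must be numeric")
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0)
    hf_stop("empty phenotype group")
  if (length(group_a) < 2 || length(group_b) < 2) {
    res <- list(line_id = line_id, verdict = "inconclusive", p_value = NA_real_,
                alpha = alpha, method = method,
                mean_a = mean(group_a), mean_b = mean(group_b),
                n_a = length(group_a), n_b = length(group_b))
    class(res) <- "segregation_call"
    return(res)
  }
  p <- tryCatch(
    stats::t.test(group_a, group_b)$p.value,
    error = function(e) {
      # both groups essentially constant: decide on the means
      if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1 else 0
    }
  )
  res <- list(
    line_id = line_id,
    verdict = if (p < alpha) "segregating" else "non_segregating",
    p_value = p, alpha = alpha, method = method,
    mean_a = mean(group_a), mean_b = mean(group_b),
    n_a = length(group_a), n_b = length(group_b)
  )
  class(res) <- "segregation_call"
  res
}

#' @export
print.segregation_call <- function(x, ...) {
  cat(sprintf("segregation call%s: %s (Welch t, p = %s, alpha = %g, %s)\n",
              if (is.na(x$line_id)) "" else paste0(" [", x$line_id, "]"),
              x$verdict,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4),
              x$alpha, x$method))
  invisible(x)
}
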