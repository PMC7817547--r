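# CSV readers with schema validation (RFC-4180, UTF-8, header row, "." as
# decimal point). Each reader reports offending rows by line number.

read_csv_checked <- function(path, required, numeric_cols = character(0)) {
  hf_assert(file.exists(path), sprintf("file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    hf_stop(sprintf("%s: missing required column(s): %s", path,
                    paste(missing, collapse = ", ")))
  }
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    bad <- which(is.na(v) & !is.na(x[[cc]]) & x[[cc]] != "")
    if (length(bad)) {
      hf_stop(sprintf("%s: non-numeric value '%s' in column '%s' (data row %d)",
                      path, x[[cc]][bad[1]], cc, bad[1]))
    }
    x[[cc]] <- v
  }
  x
}

#' Read a marker map CSV
#'
#' Expected header: `marker,chrom,pos_bp`.
#' @param path CSV file path
#' @return a [marker_map()]
#' @export
read_marker_map <- function(path) {
  x <- read_csv_checked(path, c("marker", "chrom", "pos_bp"), "pos_bp")
  marker_map(x$marker, x$chrom, x$pos_bp)
}

#' Read a genotype table CSV
#'
#' First column `line_id`; remaining columns are marker ids matching the
#' map, cells in `A`, `B`, `H`, `U`. Invalid cells are reported with row and
#' column.
#' @param path CSV file path
#' @param map a [marker_map()]
#' @return a [genotype_table()]
#' @export
read_genotype_table <- function(path, map) {
  x <- read_csv_checked(path, "line_id")
  missing <- setdiff(map$marker, names(x))
  if (length(missing)) {
    hf_stop(sprintf("%s: genotype table lacks marker column(s): %s", path,
                    paste(missing, collapse = ", ")))
  }
  genotype_table(x$line_id, as.matrix(x[, map$marker, drop = FALSE]), map)
}

#' Read fixed-progeny phenotypes
#'
#' Expected header: `line_id,allele,value` with `allele` in `A`/`B`: the
#' phenotypes of progeny fixed for either parental allele at each tested
#' recombinant line.
#' @param path CSV file path
#' @return validated data.frame
#' @export
read_progeny_phenotypes <- function(path) {
  x <- read_csv_checked(path, c("line_id", "allele", "value"), "value")
  bad <- which(!x$allele %in% c("A", "B"))
  if (length(bad)) {
    hf_stop(sprintf("%s: allele must be 'A' or 'B' (data row %d has '%s')",
                    path, bad[1], x$allele[bad[1]]))
  }
  x
}

#' Read segregation calls
#'
#' Expected header: `line_id,start_bp,end_bp,verdict,p_value,method`.
#' @param path CSV file path
#' @return validated data.frame
#' @export
read_segregation_calls <- function(path) {
  x <- read_csv_checked(path, c("line_id", "start_bp", "end_bp", "verdict"),
                        c("start_bp", "end_bp"))
  bad <- which(!x$verdict %in% c("segregating", "non_segregating", "inconclusive"))
  if (length(bad)) {
    hf_stop(sprintf("%s: unknown verdict '%s' (data row %d)", path,
                    x$verdict[bad[1]], bad[1]))
  }
  x
}

#' Read an organ-sample table for labeling experiments
#'
#' Expected header: `plant_id,genotype,experiment,organ,dw_mg,n_pct,a15n_pct`;
#' unlabeled controls are rows with `experiment = "control"`. Duplicate
#' (plant, organ) pairs and non-positive dry weights are errors.
#' @param path CSV file path
#' @return validated data.frame
#' @export
read_organ_samples <- function(path) {
  x <- read_csv_checked(
    path,
    c("plant_id", "genotype", "experiment", "organ", "dw_mg", "n_pct", "a15n_pct"),
    c("dw_mg", "n_pct", "a15n_pct"))
  bad <- which(!(x$dw_mg > 0))
  if (length(bad)) {
    hf_stop(sprintf("%s: non-positive dry weight (data row %d)", path, bad[1]))
  }
  bad <- which(x$n_pct < 0 | x$n_pct > 100 | x$a15n_pct < 0 | x$a15n_pct > 100)
  if (length(bad)) {
    hf_stop(sprintf("%s: percent out of [0, 100] (data row %d)", path, bad[1]))
  }
  dup <- which(duplicated(x[, c("plant_id", "experiment", "organ")]))
  if (length(dup)) {
    hf_stop(sprintf("%s: duplicate (plant, organ) pair %s/%s (data row %d)",
                    path, x$plant_id[dup[1]], x$organ[dup[1]], dup[1]))
  }
  x
}

#' Read senescence scores
#'
#' Expected header: `plant_id,genotype,das,n_yellow,n_total_at_bolting`.
#' @param path CSV file path
#' @return data.frame with an added `fraction` column
#' @export
read_senescence_scores <- function(path) {
  x <- read_csv_checked(
    path, c("plant_id", "genotype", "das", "n_yellow", "n_total_at_bolting"),
    c("das", "n_yellow", "n_total_at_bolting"))
  x$fraction <- senescent_leaf_fraction(x$n_yellow, x$n_total_at_bolting)
  x
}

#' Read chlorophyll kinetics series
#'
#' Expected header:
#' `plant_id,leaf_rank,das,chl_index,flower_bud_das` (a `genotype` column is
#' kept when present).
#' @param path CSV file path
#' @return validated data.frame
#' @export
read_chlorophyll_series <- function(path) {
  read_csv_checked(
    path, c("plant_id", "leaf_rank", "das", "chl_index", "flower_bud_das"),
    c("leaf_rank", "das", "chl_index", "flower_bud_das"))
}

#' Write a table as CSV
#'
#' Locale-independent (decimal point, no row names).
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
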