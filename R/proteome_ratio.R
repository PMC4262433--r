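check_proteome <- function(table) {
  req <- c("protein_id", "abundance_wt", "abundance_ko", "peptides")
  if (!all(req %in% names(table)))
    stop("proteome table must have columns ", paste(req, collapse = ", "))
  invisible(table)
}

#' Filter proteins by peptide support
#'
#' Quantitative values are only trusted for proteins quantified by a minimum
#' number of peptides (2 by default); single-peptide identifications are
#' dropped. The number of removed rows is stored in `attr(, "n_removed")`.
#'
#' @param table proteome data frame (columns `protein_id`, `abundance_wt`,
#'   `abundance_ko`, `peptides`, optionally `confidence`).
#' @param min_peptides minimum peptide count to retain a row.
#' @return the filtered table.
#' @export
filter_quantifiable <- function(table, min_peptides = 2L) {
  check_proteome(table)
  keep <- table$peptides >= min_peptides
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' WT/KO abundance ratios with a floor for ablated proteins
#'
#' Ratio of mean normalized WT abundance over KO abundance per protein. A
#' genuinely ablated protein has a KO abundance at (or below) the noise
#' floor; to keep its ratio finite the KO denominator is floored at
#' `floor_fraction` times the median nonzero abundance of the table, and
#' floored rows are flagged. Rows with zero abundance in both genotypes
#' cannot be quantified and get an `NA` ratio with `not_quantifiable = TRUE`.
#'
#' @inheritParams filter_quantifiable
#' @param floor_fraction denominator floor, as a fraction of the median
#'   nonzero abundance.
#' @return the table with added columns `ratio`, `log10_ratio`, `log10_wt`,
#'   `log10_ko`, `floored`, `not_quantifiable`.
#' @export
abundance_ratio <- function(table, floor_fraction = 1e-3) {
  check_proteome(table)
  if (any(table$abundance_wt < 0) || any(table$abundance_ko < 0))
    stop("abundances must be >= 0")
  pool <- c(table$abundance_wt, table$abundance_ko)
  pool <- pool[pool > 0]
  floor_val <- if (length(pool)) floor_fraction * stats::median(pool) else 0
  nq <- table$abundance_wt == 0 & table$abundance_ko == 0
  denom <- pmax(table$abundance_ko, floor_val)
  table$ratio <- ifelse(nq, NA_real_, table$abundance_wt / denom)
  table$log10_ratio <- log10(table$ratio)
  table$log10_wt <- ifelse(table$abundance_wt > 0,
                           log10(table$abundance_wt), NA_real_)
  table$log10_ko <- ifelse(table$abundance_ko > 0,
                           log10(table$abundance_ko), NA_real_)
  table$floored <- !nq & table$abundance_ko < floor_val
  table$not_quantifiable <- nq
  attr(table, "floor") <- floor_val
  table
}

#' Classify proteins against the 2-fold bands
#'
#' The scatter of log abundances is read against the diagonal 2-fold bands:
#' a protein is `within` when 0.5 <= WT/KO <= 2 (boundaries inclusive),
#' `above` when the ratio exceeds 2, `below` under 0.5. Class counts are
#' stored in `attr(, "class_counts")`.
#'
#' @param table output of [abundance_ratio()] (must carry a `ratio` column).
#' @return the table with an added `class` column.
#' @export
classify_two_fold <- function(table) {
  if (!"ratio" %in% names(table))
    stop("run abundance_ratio() first: no 'ratio' column")
  cls <- ifelse(is.na(table$ratio), NA_character_,
                ifelse(table$ratio > 2, "above",
                       ifelse(table$ratio < 0.5, "below", "within")))
  table$class <- cls
  attr(table, "class_counts") <- table(factor(cls, c("below", "within", "above")))
  table
}

#' Check that the proteome is unchanged apart from known exclusions
#'
#' The composition claim — the organelle proteome is unaltered in the
#' knockout — holds when every protein except the deliberately excluded ids
#' (e.g. the ablated gene product) classifies as `within` the 2-fold bands.
#'
#' @param table output of [classify_two_fold()] (classification is applied
#'   on the fly if missing).
#' @param excluded_ids protein ids exempt from the check.
#' @return list with `unchanged` (logical) and `offenders` (ids outside the
#'   band, excluding the exempt ones).
#' @export
unchanged_proteome_check <- function(table, excluded_ids = character()) {
  if (!"class" %in% names(table)) {
    if (!"ratio" %in% names(table)) table <- abundance_ratio(table)
    table <- classify_two_fold(table)
  }
  consider <- !(table$protein_id %in% excluded_ids)
  off <- table$protein_id[consider &
                            (is.na(table$class) | table$class != "within")]
  list(unchanged = length(off) == 0L, offenders = off)
}
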