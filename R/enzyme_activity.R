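check_activity <- function(table) {
  req <- c("genotype", "fraction", "glucose", "enzyme",
           "mean_mU_per_mg", "sem", "n")
  if (!all(req %in% names(table)))
    stop("activity table must have columns ", paste(req, collapse = ", "))
  if (any(table$mean_mU_per_mg <= 0)) stop("activities must be > 0")
  if (any(table$sem < 0)) stop("SEMs must be >= 0")
  invisible(table)
}

activity_row <- function(table, enzyme, genotype, fraction, glucose) {
  hit <- table$enzyme == enzyme & table$genotype == genotype &
    table$fraction == fraction & table$glucose == glucose
  if (sum(hit) != 1L)
    stop("no activity row for (", enzyme, ", ", genotype, ", ", fraction,
         ", ", glucose, ")")
  table[hit, , drop = FALSE]
}

ratio_with_error <- function(num, den) {
  ratio <- num$mean_mU_per_mg / den$mean_mU_per_mg
  rel <- sqrt((num$sem / num$mean_mU_per_mg)^2 +
                (den$sem / den$mean_mU_per_mg)^2)
  list(ratio = ratio, se = ratio * rel)
}

# non-overlap of the two mean +- 2 SEM intervals
intervals_separate <- function(a, b) {
  a_lo <- a$mean_mU_per_mg - 2 * a$sem; a_hi <- a$mean_mU_per_mg + 2 * a$sem
  b_lo <- b$mean_mU_per_mg - 2 * b$sem; b_hi <- b$mean_mU_per_mg + 2 * b$sem
  a_lo > b_hi || b_lo > a_hi
}

#' Glycosomal enrichment factor of an enzyme activity
#'
#' Ratio of the specific activity in the glycosome-enriched fraction over
#' the whole-cell extract, for one enzyme/genotype/glucose combination. A
#' genuinely glycosomal enzyme (marker GPDH) enriches several-fold with the
#' organelle; an activity that barely enriches is mostly extraglycosomal.
#' The relative standard error is propagated assuming independent numerator
#' and denominator.
#'
#' @param table activity data frame (see [gen_activity_table()] for the
#'   schema).
#' @param enzyme,genotype,glucose row selectors (`"HADH"`/`"GPDH"`,
#'   `"WT"`/`"KO"`, `"+gluc"`/`"-gluc"`).
#' @return list with `ratio` (glyco/WCE) and `se`.
#' @examples
#' enrichment_factor(gen_activity_table(), "GPDH", "WT", "+gluc")$ratio
#' @export
enrichment_factor <- function(table, enzyme, genotype, glucose) {
  check_activity(table)
  glyco <- activity_row(table, enzyme, genotype, "glyco", glucose)
  wce <- activity_row(table, enzyme, genotype, "WCE", glucose)
  ratio_with_error(glyco, wce)
}

#' WT/KO contrast of an enzyme activity
#'
#' Ratio of WT over knockout specific activity for one
#' enzyme/fraction/glucose combination, with propagated error and an
#' `indistinguishable` flag set when the two mean +- 2 SEM intervals
#' overlap (the operational reading of "not significantly different" when
#' only summary statistics are available).
#'
#' @inheritParams enrichment_factor
#' @param fraction `"WCE"` or `"glyco"`.
#' @return list with `ratio` (WT/KO), `se`, `indistinguishable`.
#' @export
genotype_contrast <- function(table, enzyme, fraction, glucose) {
  check_activity(table)
  wt <- activity_row(table, enzyme, "WT", fraction, glucose)
  ko <- activity_row(table, enzyme, "KO", fraction, glucose)
  out <- ratio_with_error(wt, ko)
  out$indistinguishable <- !intervals_separate(wt, ko)
  out
}

#' Glucose-condition contrast of an enzyme activity
#'
#' Ratio of the +glucose over the glucose-depleted specific activity for one
#' enzyme/genotype/fraction combination, with the same overlap flag as
#' [genotype_contrast()].
#'
#' @inheritParams genotype_contrast
#' @return list with `ratio` (+gluc/-gluc), `se`, `indistinguishable`.
#' @export
glucose_contrast <- function(table, enzyme, genotype, fraction) {
  check_activity(table)
  plus <- activity_row(table, enzyme, genotype, fraction, "+gluc")
  minus <- activity_row(table, enzyme, genotype, fraction, "-gluc")
  out <- ratio_with_error(plus, minus)
  out$indistinguishable <- !intervals_separate(plus, minus)
  out
}
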