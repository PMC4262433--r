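#' Summarize a per-cell lipid-droplet count sample
#'
#' @param sample either a numeric vector of per-cell counts or a data frame
#'   with a `count` column (the ld_counts schema).
#' @return list with `mean`, `max`, and `histogram` (relative frequency of
#'   each observed count, summing to 1).
#' @examples
#' summarize_counts(c(0, 1, 1, 2, 9))
#' @export
summarize_counts <- function(sample) {
  counts <- if (is.data.frame(sample)) sample$count else sample
  if (is.null(counts) || length(counts) == 0L)
    stop("empty LD-count sample")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("LD counts must be non-negative integers")
  hist <- table(factor(counts, levels = 0:max(counts)))
  list(mean = mean(counts),
       max = max(counts),
       histogram = prop.table(hist))
}

#' Fed/unfed fold change with bootstrap confidence interval
#'
#' Point estimate is the ratio of arithmetic means of replicate-level values
#' (values normalized to the control), with a seeded nonparametric percentile
#' bootstrap over replicates for the confidence interval. Resampled
#' deviations from the observed means are expanded by `sqrt(n/(n-1))`,
#' correcting the `(n-1)/n` variance shrinkage of the bootstrap at the
#' triplicate scale these experiments run at.
#'
#' @param treated,control numeric vectors of replicate-level means
#'   (strictly positive).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed recorded in the output.
#' @param conf_level confidence level of the percentile interval.
#' @return object of class `fold_change_estimate` with `point`, `lower`,
#'   `upper`, `n_boot`, `seed`, `conf_level`.
#' @examples
#' fold_change(c(4.6, 4.7, 4.5), c(1.0, 0.98, 1.02), seed = 1)
#' @export
fold_change <- function(treated, control, n_boot = 1000L, seed = 1L,
                        conf_level = 0.95) {
  if (length(treated) == 0L || length(control) == 0L)
    stop("treated and control must be non-empty")
  if (any(treated <= 0) || any(control <= 0))
    stop("all replicate values must be > 0")
  point <- mean(treated) / mean(control)
  mt <- mean(treated); mc <- mean(control)
  et <- if (length(treated) > 1) sqrt(length(treated) / (length(treated) - 1)) else 1
  ec <- if (length(control) > 1) sqrt(length(control) / (length(control) - 1)) else 1
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      tb <- treated[sample.int(length(treated), replace = TRUE)]
      cb <- control[sample.int(length(control), replace = TRUE)]
      num <- mt + et * (mean(tb) - mt)
      den <- mc + ec * (mean(cb) - mc)
      num / den
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  out <- list(point = point, lower = min(ci[1], point),
              upper = max(ci[2], point),
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              conf_level = conf_level)
  class(out) <- "fold_change_estimate"
  out
}

#' @export
print.fold_change_estimate <- function(x, ...) {
  cat(sprintf("fold change %.3g  [%.3g, %.3g] %g%% bootstrap CI (%d resamples, seed %d)\n",
              x$point, x$lower, x$upper, 100 * x$conf_level, x$n_boot,
              x$seed))
  invisible(x)
}

#' Cross-modality concordance of induction fold changes
#'
#' The storage interpretation rests on microscopy LD counts, flow cytometry
#' and TAG densitometry reporting the same induction factor. This report
#' collects the three estimates and flags concordance when the largest
#' pairwise ratio of point estimates stays at or below `tolerance`.
#'
#' @param ld,flow,tag [fold_change()] estimates (or bare positive numbers).
#' @param tolerance maximum pairwise ratio still called concordant.
#' @return list with `estimates`, `max_pairwise_ratio`, `tolerance`,
#'   `concordant`.
#' @export
concordance_report <- function(ld, flow, tag, tolerance = 1.15) {
  pt <- function(x) if (inherits(x, "fold_change_estimate")) x$point else x
  est <- c(ld = pt(ld), flow = pt(flow), tag = pt(tag))
  if (any(est <= 0)) stop("fold-change estimates must be > 0")
  ratio <- max(est) / min(est)
  structure(list(estimates = est,
                 max_pairwise_ratio = ratio,
                 tolerance = tolerance,
                 concordant = ratio <= tolerance),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Induction fold changes: LD count ", signif(x$estimates["ld"], 3),
      ", flow ", signif(x$estimates["flow"], 3),
      ", TAG ", signif(x$estimates["tag"], 3), "\n", sep = "")
  cat(sprintf("max pairwise ratio %.3f (tolerance %.2f): %s\n",
              x$max_pairwise_ratio, x$tolerance,
              if (x$concordant) "concordant" else "discordant"))
  invisible(x)
}
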