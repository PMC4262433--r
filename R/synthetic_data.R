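#' Synthetic per-cell lipid-droplet counts
#'
#' Draws one population of per-cell LD counts for the given feeding condition.
#' Counts follow a binomial distribution with size `ld_max` and success
#' probability chosen to hit the target mean (`unfed_ld_mean`, or
#' `unfed_ld_mean * ld_fold` when fed). The binomial gives the bell-shaped,
#' bounded distribution seen in per-cell LD histograms without ad hoc
#' truncation: no cell can ever exceed the hard maximum.
#'
#' @param config a [study_config()].
#' @param condition `"fed"` (oleate-fed) or `"unfed"` (control).
#' @return data frame with columns `cell_id`, `condition`, `count`.
#' @examples
#' fed <- gen_ld_counts(study_config(seed = 1), "fed")
#' mean(fed$count)
#' @export
gen_ld_counts <- function(config, condition = c("unfed", "fed")) {
  validate_study_config(config)
  condition <- match.arg(condition)
  mu <- config$unfed_ld_mean * if (condition == "fed") config$ld_fold else 1
  if (mu > config$ld_max)
    stop("configuration error: target mean LD count (", signif(mu, 4),
         ") exceeds ld_max (", config$ld_max, ")")
  counts <- withr::with_seed(
    gen_seed(config, "ld", condition),
    stats::rbinom(config$n_cells, size = config$ld_max, prob = mu / config$ld_max)
  )
  data.frame(cell_id = seq_len(config$n_cells),
             condition = condition,
             count = counts,
             stringsAsFactors = FALSE)
}

#' Synthetic whole-cell flow-cytometry fluorescence
#'
#' Emulates flow cytometry of lipophilic-dye-stained cells: the cytometer
#' integrates fluorescence over the whole cell, so each cell's signal is the
#' background (membrane staining) plus the summed intensity of its droplets,
#' each droplet contributing a lognormal intensity with mean
#' `droplet_intensity` and CV `droplet_cv`. The fed population's mean droplet
#' count is set so that the expected fed/unfed whole-cell ratio equals
#' `flow_fold` exactly, given the configured background.
#'
#' @inheritParams gen_ld_counts
#' @return data frame with columns `cell_id`, `condition`, `intensity`.
#' @export
gen_flow_population <- function(config, condition = c("unfed", "fed")) {
  validate_study_config(config)
  condition <- match.arg(condition)
  bg <- config$flow_background
  ds <- config$droplet_intensity
  m_unfed <- config$unfed_ld_mean
  mu <- if (condition == "fed") {
    # target mean count so that E[fed]/E[unfed] = flow_fold
    (config$flow_fold * (bg + m_unfed * ds) - bg) / ds
  } else {
    m_unfed
  }
  if (mu > config$ld_max)
    stop("configuration error: flow_fold requires a mean droplet count (",
         signif(mu, 4), ") above ld_max (", config$ld_max, ")")
  intensity <- withr::with_seed(gen_seed(config, "flow", condition), {
    counts <- stats::rbinom(config$n_cells, config$ld_max, mu / config$ld_max)
    per_droplet <- ds * rlnorm_cv(sum(counts), config$droplet_cv)
    droplet_signal <- numeric(config$n_cells)
    if (sum(counts) > 0) {
      sums <- rowsum(per_droplet, rep(seq_len(config$n_cells), counts))
      droplet_signal[as.integer(rownames(sums))] <- sums[, 1]
    }
    bg + droplet_signal
  })
  data.frame(cell_id = seq_len(config$n_cells),
             condition = condition,
             intensity = intensity,
             stringsAsFactors = FALSE)
}

#' Synthetic exponential growth curve
#'
#' Cell densities follow `growth_n0 * 2^(t / Td)` with multiplicative
#' lognormal noise of CV `noise_cv` (mean-unbiased), sampled at
#' `growth_timepoints_h`.
#'
#' @inheritParams gen_ld_counts
#' @return data frame with columns `time_h`, `density_cells_per_ml`.
#' @export
gen_growth_curve <- function(config) {
  validate_study_config(config)
  t <- config$growth_timepoints_h
  if (length(t) < 2L || any(diff(t) <= 0))
    stop("growth_timepoints_h must be strictly increasing")
  dens <- withr::with_seed(gen_seed(config, "growth"), {
    config$growth_n0 * 2^(t / config$doubling_time_h) *
      rlnorm_cv(length(t), config$noise_cv)
  })
  data.frame(time_h = t, density_cells_per_ml = dens)
}

#' Synthetic stored-signal decay after substrate withdrawal
#'
#' Samples the kinetic turnover model
#' `S(t) = B + (1 - B) * exp(-(mu + k) t)` with `mu = ln(2)/Td`,
#' `k = catabolic_rate_h` and `B = basal_level`, at `decay_timepoints_h`,
#' with `replicates` independent replicates per timepoint and multiplicative
#' lognormal noise of CV `noise_cv`. The t = 0 fed signal is 1 by
#' construction (up to noise).
#'
#' @inheritParams gen_ld_counts
#' @return data frame with columns `time_h`, `replicate`, `signal`.
#' @export
gen_decay_experiment <- function(config) {
  validate_study_config(config)
  t <- config$decay_timepoints_h
  if (!0 %in% t) stop("decay_timepoints_h must include t = 0")
  mu <- log(2) / config$doubling_time_h
  k <- config$catabolic_rate_h
  b <- config$basal_level
  truth <- b + (1 - b) * exp(-(mu + k) * t)
  out <- expand.grid(replicate = seq_len(config$replicates), time_h = t,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$time_h, out$replicate), c("time_h", "replicate")]
  out$signal <- withr::with_seed(gen_seed(config, "decay"), {
    rep(truth[match(out$time_h, t)], 1) * rlnorm_cv(nrow(out), config$noise_cv)
  })
  rownames(out) <- NULL
  out
}

# deterministic catalogue of carbon:double-bond classes, dominant ones first
tag_catalog <- function(config) {
  grid <- expand.grid(db = 0:8, c = seq(42, 62, by = 2),
                      KEEP.OUT.ATTRS = FALSE)
  labels <- sprintf("%d:%d", grid$c, grid$db)
  dom <- names(config$dominant_classes)
  if (!all(dom %in% labels))
    stop("dominant_classes outside the supported catalogue: ",
         paste(setdiff(dom, labels), collapse = ", "))
  rest <- setdiff(labels, dom)
  n_rest <- config$n_tag_species - length(dom)
  if (n_rest > length(rest))
    stop("n_tag_species exceeds the catalogue size (", length(labels), ")")
  c(dom, rest[seq_len(n_rest)])
}

#' Synthetic shotgun-lipidomics TAG species table
#'
#' Produces a species-intensity table of `n_tag_species` distinct TAG species
#' plus a spiked 17:0/17:0/17:0 internal standard. Classes named in
#' `dominant_classes` carry the configured shares of total intensity; the
#' remaining species split the rest with geometrically decreasing weights.
#' In the fed condition the dominant classes (the oleate sinks) are scaled by
#' `tag_fold` while the standard spike is unchanged, so standard-normalized
#' dominant intensities increase with feeding.
#'
#' @inheritParams gen_ld_counts
#' @return data frame with columns `species_label`, `intensity`,
#'   `is_standard`.
#' @export
gen_lipidome <- function(config, condition = c("unfed", "fed")) {
  validate_study_config(config)
  condition <- match.arg(condition)
  species <- tag_catalog(config)
  n_dom <- length(config$dominant_classes)
  w <- numeric(length(species))
  w[seq_len(n_dom)] <- config$dominant_classes
  rest <- (1 - sum(config$dominant_classes)) *
    local({
      g <- 0.97^seq_len(length(species) - n_dom)
      g / sum(g)
    })
  w[-seq_len(n_dom)] <- rest
  total <- 1e6
  intensity <- withr::with_seed(gen_seed(config, "lipidome", condition), {
    base <- total * w * rlnorm_cv(length(w), config$noise_cv)
    if (condition == "fed")
      base[seq_len(n_dom)] <- base[seq_len(n_dom)] * config$tag_fold
    base
  })
  out <- data.frame(species_label = c(species, "17:0/17:0/17:0"),
                    intensity = c(intensity, 5e4),
                    is_standard = c(rep(FALSE, length(species)), TRUE),
                    stringsAsFactors = FALSE)
  out
}

#' Synthetic two-genotype label-free proteome table
#'
#' `n_proteins` proteins with lognormal WT abundances; all but one have a
#' true WT/KO ratio of 1 with lognormal scatter (`proteome_cv`), and exactly
#' one — the ablated protein, id `"TFEA1"` — has KO abundance at a noise
#' floor of WT/`ablated_ratio`, so its computed ratio is finite and close to
#' `ablated_ratio` by construction. A `singleton_fraction` of the remaining
#' proteins carries a single supporting peptide to exercise the
#' minimum-2-peptides filter.
#'
#' @inheritParams gen_ld_counts
#' @return data frame with columns `protein_id`, `abundance_wt`,
#'   `abundance_ko`, `peptides`, `confidence`; the ablated protein id is
#'   recorded in `attr(, "ablated_id")`.
#' @export
gen_proteome_table <- function(config) {
  validate_study_config(config)
  n <- config$n_proteins
  withr::with_seed(gen_seed(config, "proteome"), {
    wt <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1)
    ko <- wt * stats::rlnorm(n, meanlog = 0, sdlog = config$proteome_cv)
    peptides <- 2L + stats::rpois(n, lambda = 5)
    idx_ablated <- sample.int(n, 1L)
    ko[idx_ablated] <- wt[idx_ablated] / config$ablated_ratio *
      rlnorm_cv(1, 0.02)
    peptides[idx_ablated] <- max(peptides[idx_ablated], 5L)
    n_single <- round(config$singleton_fraction * (n - 1L))
    singles <- sample(setdiff(seq_len(n), idx_ablated), n_single)
    peptides[singles] <- 1L
    ids <- sprintf("GP%03d", seq_len(n))
    ids[idx_ablated] <- "TFEA1"
    out <- data.frame(protein_id = ids,
                      abundance_wt = wt,
                      abundance_ko = ko,
                      peptides = peptides,
                      confidence = round(peptides * stats::runif(n, 15, 60), 1),
                      stringsAsFactors = FALSE)
    attr(out, "ablated_id") <- "TFEA1"
    out
  })
}

# Published specific activities (mU/mg protein, mean +- SEM of n experiments)
# for NADPH-dependent 3-hydroxyacyl-CoA dehydrogenase (HADH) and the
# glycosomal marker glycerol-3-phosphate dehydrogenase (GPDH), by genotype,
# fraction and glucose condition. Stored verbatim as a fixture; glycosome
# fractions were only assayed under glucose-rich conditions.
activity_table1 <- function() {
  tbl <- rbind(
    c("WT", "WCE",   "+gluc", "HADH",   6.62, 0.63, 5),
    c("WT", "WCE",   "-gluc", "HADH",   5.22, 0.40, 5),
    c("KO", "WCE",   "+gluc", "HADH",   6.04, 0.71, 5),
    c("KO", "WCE",   "-gluc", "HADH",   5.00, 0.47, 5),
    c("WT", "glyco", "+gluc", "HADH",  11.76, 0.52, 6),
    c("KO", "glyco", "+gluc", "HADH",   9.12, 0.77, 6),
    c("WT", "WCE",   "+gluc", "GPDH",  32.20, 3.48, 3),
    c("WT", "WCE",   "-gluc", "GPDH",  34.92, 2.71, 3),
    c("KO", "WCE",   "+gluc", "GPDH",  22.80, 2.45, 3),
    c("KO", "WCE",   "-gluc", "GPDH",  35.40, 1.89, 3),
    c("WT", "glyco", "+gluc", "GPDH", 213.18, 4.12, 3),
    c("KO", "glyco", "+gluc", "GPDH", 208.22, 12.19, 3)
  )
  data.frame(genotype = tbl[, 1], fraction = tbl[, 2], glucose = tbl[, 3],
             enzyme = tbl[, 4],
             mean_mU_per_mg = as.numeric(tbl[, 5]),
             sem = as.numeric(tbl[, 6]),
             n = as.integer(tbl[, 7]),
             stringsAsFactors = FALSE)
}

#' Enzyme specific-activity table (published summary fixture)
#'
#' Returns the specific-activity summary table (mean, SEM, n in mU/mg of
#' protein) for HADH and the glycosomal marker GPDH across genotype, fraction
#' and glucose condition. These are summary statistics stored verbatim, not
#' resampled, because only means and SEMs — never raw replicates — were
#' reported.
#'
#' @inheritParams gen_ld_counts
#' @return data frame with columns `genotype`, `fraction`, `glucose`,
#'   `enzyme`, `mean_mU_per_mg`, `sem`, `n`.
#' @export
gen_activity_table <- function(config = study_config()) {
  validate_study_config(config)
  activity_table1()
}

# Band map of the HPTLC separation (hexane/ethylether/acetic acid 90:15:2):
# phospholipids stay at the origin; DAG, FFA, TAG and steryl esters migrate
# at the listed retardation factors.
tlc_band_map <- function() {
  data.frame(band = c("PL", "DAG", "FFA", "TAG", "SE"),
             rf = c(0, 0.08, 0.29, 0.50, 0.90),
             base_area = c(2.0, 0.25, 0.40, 1.0, 0.15),
             stringsAsFactors = FALSE)
}

#' Synthetic TLC densitometry lanes
#'
#' Generates densitometry readings for `replicates` lanes of a lipid-extract
#' HPTLC separation. Bands sit at the retardation factors of the standard
#' neutral-lipid system (phospholipids at the origin, DAG at R_F 0.08, free
#' fatty acids at 0.29, TAG at 0.50, steryl esters at 0.90). Areas are
#' normalized so the unfed TAG band has unit expected area; feeding scales
#' the TAG band by `tag_fold`. Replicate noise is multiplicative lognormal
#' with CV `noise_cv`.
#'
#' @inheritParams gen_ld_counts
#' @return data frame with columns `condition`, `replicate`, `rf`, `area`.
#' @export
gen_tlc_lane <- function(config, condition = c("unfed", "fed")) {
  validate_study_config(config)
  condition <- match.arg(condition)
  bands <- tlc_band_map()
  base <- bands$base_area
  base[bands$band == "TAG"] <- base[bands$band == "TAG"] *
    if (condition == "fed") config$tag_fold else 1
  out <- expand.grid(rf = bands$rf, replicate = seq_len(config$replicates),
                     KEEP.OUT.ATTRS = FALSE)
  out$area <- withr::with_seed(gen_seed(config, "tlc", condition), {
    rep(base, config$replicates) * rlnorm_cv(nrow(out), config$noise_cv)
  })
  data.frame(condition = condition,
             replicate = out$replicate,
             rf = out$rf,
             area = out$area,
             stringsAsFactors = FALSE)
}
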