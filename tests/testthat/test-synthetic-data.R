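test_that("generators are deterministic under a fixed config", {
  cfg <- small_config(seed = 7L)
  expect_identical(gen_ld_counts(cfg, "fed"), gen_ld_counts(cfg, "fed"))
  expect_identical(gen_flow_population(cfg, "unfed"),
                   gen_flow_population(cfg, "unfed"))
  expect_identical(gen_growth_curve(cfg), gen_growth_curve(cfg))
  expect_identical(gen_decay_experiment(cfg), gen_decay_experiment(cfg))
  expect_identical(gen_lipidome(cfg, "fed"), gen_lipidome(cfg, "fed"))
  expect_identical(gen_proteome_table(cfg), gen_proteome_table(cfg))
  expect_identical(gen_tlc_lane(cfg, "fed"), gen_tlc_lane(cfg, "fed"))
  # and a different seed changes the draw
  cfg2 <- small_config(seed = 8L)
  expect_false(identical(gen_ld_counts(cfg, "fed"), gen_ld_counts(cfg2, "fed")))
})

test_that("LD counts are bounded integers with the configured fold", {
  cfg <- study_config(seed = 11L)
  fed <- gen_ld_counts(cfg, "fed")
  unf <- gen_ld_counts(cfg, "unfed")
  expect_true(all(fed$count >= 0 & fed$count <= cfg$ld_max))
  expect_true(all(fed$count == round(fed$count)))
  # the per-cell maximum of nine is reached in a fed population of 10000
  expect_identical(max(fed$count), 9L)
  expect_equal(mean(fed$count) / mean(unf$count), 4.7, tolerance = 0.2 / 4.7)
  # identity case: ld_fold = 1 gives indistinguishable populations
  cfg1 <- study_config(seed = 11L, ld_fold = 1)
  f1 <- gen_ld_counts(cfg1, "fed")$count
  u1 <- gen_ld_counts(cfg1, "unfed")$count
  se <- sqrt(var(f1) / length(f1) + var(u1) / length(u1))
  expect_lt(abs(mean(f1) - mean(u1)), 3 * se)
  # a fed mean above the hard maximum is a configuration error
  expect_error(gen_ld_counts(study_config(unfed_ld_mean = 2, ld_fold = 5), "fed"),
               "exceeds ld_max")
})

test_that("flow populations honour the configured fluorescence fold", {
  cfg <- study_config(seed = 3L)
  fed <- gen_flow_population(cfg, "fed")
  unf <- gen_flow_population(cfg, "unfed")
  expect_true(all(fed$intensity > 0))
  expect_equal(mean(fed$intensity) / mean(unf$intensity), 4.6,
               tolerance = 0.2 / 4.6)
  # flow_fold = 1 collapses the fed/unfed contrast
  cfg1 <- study_config(seed = 3L, flow_fold = 1)
  r1 <- mean(gen_flow_population(cfg1, "fed")$intensity) /
    mean(gen_flow_population(cfg1, "unfed")$intensity)
  expect_equal(r1, 1, tolerance = 0.05)
  # degenerate case: no background, exactly one droplet per cell
  cfg0 <- small_config(flow_background = 0, unfed_ld_mean = 1, ld_max = 1L,
                       droplet_cv = 0)
  one <- gen_flow_population(cfg0, "unfed")
  expect_equal(mean(one$intensity), cfg0$droplet_intensity, tolerance = 1e-9)
})

test_that("growth curves follow exponential doubling", {
  cfg0 <- small_config(noise_cv = 0, doubling_time_h = 12,
                       growth_timepoints_h = c(0, 12, 24))
  g <- gen_growth_curve(cfg0)
  expect_equal(g$density_cells_per_ml[1], cfg0$growth_n0)
  expect_equal(g$density_cells_per_ml[3], 4 * cfg0$growth_n0)
  expect_error(gen_growth_curve(small_config(growth_timepoints_h = c(0, 8, 8))),
               "strictly increasing")
  expect_true(all(gen_growth_curve(small_config())$density_cells_per_ml > 0))
})

test_that("decay experiments sample the kinetic model", {
  # one halving after one doubling time under pure dilution
  cfg0 <- small_config(noise_cv = 0, basal_level = 0, catabolic_rate_h = 0,
                       decay_timepoints_h = c(0, 12), doubling_time_h = 12,
                       replicates = 1L)
  d <- gen_decay_experiment(cfg0)
  expect_equal(d$signal[d$time_h == 12], 0.5, tolerance = 1e-12)
  # plateau at the basal level far beyond the doubling time
  cfgb <- small_config(noise_cv = 0, basal_level = 0.2,
                       decay_timepoints_h = c(0, 240), replicates = 1L)
  db <- gen_decay_experiment(cfgb)
  expect_equal(db$signal[db$time_h == 240], 0.2, tolerance = 1e-4)
  # replicate bookkeeping
  d3 <- gen_decay_experiment(small_config())
  expect_identical(nrow(d3), length(small_config()$decay_timepoints_h) * 3L)
})

test_that("the lipidome table has the configured catalogue and dominance", {
  cfg <- study_config(seed = 5L)
  unf <- gen_lipidome(cfg, "unfed")
  expect_identical(sum(!unf$is_standard), 96L)
  expect_identical(sum(unf$is_standard), 1L)
  expect_identical(anyDuplicated(unf$species_label), 0L)
  expect_true(all(unf$intensity > 0))
  fed <- gen_lipidome(cfg, "fed")
  af <- aggregate_by_class(fed)
  au <- aggregate_by_class(unf)
  expect_gt(af$normalized_intensity[af$class == "54:3"],
            au$normalized_intensity[au$class == "54:3"])
  # uniform dominance weights give a near-symmetric class profile
  classes <- sprintf("50:%d", 0:7)
  cfgu <- study_config(seed = 5L, n_tag_species = 8L,
                       dominant_classes = setNames(rep(1 / 8, 8), classes))
  shares <- aggregate_by_class(gen_lipidome(cfgu, "unfed"))$normalized_intensity
  expect_lt(max(shares), 2 * mean(shares))
})

test_that("the proteome table has one ablated protein and singleton rows", {
  cfg <- study_config(seed = 2L)
  tab <- gen_proteome_table(cfg)
  expect_identical(nrow(tab), cfg$n_proteins)
  expect_true(all(tab$peptides >= 1L))
  expect_identical(attr(tab, "ablated_id"), "TFEA1")
  abl <- tab[tab$protein_id == "TFEA1", ]
  expect_equal(abl$abundance_wt / abl$abundance_ko, 140, tolerance = 0.1)
  expect_gte(abl$peptides, 2L)
  expect_equal(sum(tab$peptides == 1L), round(0.1 * (cfg$n_proteins - 1)))
})

test_that("the activity fixture carries the published summary values", {
  tab <- gen_activity_table()
  expect_true(all(tab$mean_mU_per_mg > 0))
  row <- tab[tab$genotype == "WT" & tab$fraction == "WCE" &
               tab$glucose == "+gluc" & tab$enzyme == "HADH", ]
  expect_equal(row$mean_mU_per_mg, 6.62)
  expect_equal(row$sem, 0.63)
  expect_identical(row$n, 5L)
  marker <- tab[tab$genotype == "WT" & tab$fraction == "glyco" &
                  tab$glucose == "+gluc" & tab$enzyme == "GPDH", ]
  expect_equal(marker$mean_mU_per_mg, 213.18)
  expect_equal(marker$sem, 4.12)
  expect_identical(marker$n, 3L)
})

test_that("TLC lanes carry the neutral-lipid band map and condition scaling", {
  cfg <- study_config(seed = 9L)
  unf <- gen_tlc_lane(cfg, "unfed")
  expect_setequal(unique(unf$rf), c(0, 0.08, 0.29, 0.50, 0.90))
  expect_true(all(unf$area > 0))
  # unfed TAG band is the unit normalization anchor
  expect_equal(mean(unf$area[unf$rf == 0.50]), 1.0, tolerance = 0.15)
  fed <- gen_tlc_lane(cfg, "fed")
  fold <- mean(fed$area[fed$rf == 0.50]) / mean(unf$area[unf$rf == 0.50])
  expect_equal(fold, 4.6, tolerance = 0.2 / 4.6)
})
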