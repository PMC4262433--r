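test_that("the dilution prediction halves every doubling time", {
  td <- 12
  for (t in c(0, 3, 7.5, 18, 30)) {
    expect_equal(predict_dilution(1, td, t + td),
                 predict_dilution(1, td, t) / 2, tolerance = 1e-12)
  }
  expect_equal(predict_dilution(1, td, 0), 1)
  expect_equal(predict_dilution(1, td, td), 0.5)
  expect_equal(predict_dilution(1, td, 2 * td), 0.25)
  grid <- seq(0, 48, by = 0.5)
  expect_true(all(diff(predict_dilution(1, td, grid)) < 0))
})

test_that("the kinetic model nests the dilution model and hits its asymptote", {
  mu <- log(2) / 12
  grid <- seq(0, 60, by = 0.25)
  nested <- predict_with_basal(list(s0 = 1, b = 0, mu = mu, k = 0), grid)
  expect_lt(max(abs(nested - predict_dilution(1, 12, grid))), 1e-12)
  # steady state when starting at the basal level
  expect_equal(predict_with_basal(list(s0 = 0.3, b = 0.3, mu = mu, k = 0.1),
                                  grid),
               rep(0.3, length(grid)))
  # asymptote
  expect_equal(predict_with_basal(list(s0 = 1, b = 0.2, mu = mu, k = 0), 1e6),
               0.2, tolerance = 1e-9)
  # monotone decrease above the plateau, increase below it
  above <- predict_with_basal(list(s0 = 1, b = 0.2, mu = mu, k = 0.05), grid)
  expect_true(all(diff(above) < 0))
  below <- predict_with_basal(list(s0 = 0.05, b = 0.2, mu = mu, k = 0.05), grid)
  expect_true(all(diff(below) > 0))
})

test_that("decay series are normalized to the t = 0 mean", {
  d <- gen_decay_experiment(study_config(seed = 4L))
  ds <- as_decay_series(d)
  expect_equal(ds$summary$mean[ds$summary$time_h == 0], 1, tolerance = 1e-12)
  expect_true(all(ds$data$signal > 0))
  expect_error(as_decay_series(d[d$time_h > 0, ]), "t = 0")
})

test_that("noise-free kinetic data are recovered exactly", {
  mu <- log(2) / 12
  d <- noiseless_decay(c(0, 4, 8, 12, 16, 24, 32), b = 0.2, mu = mu, k = 0)
  fit <- fit_turnover(d, mu, n_boot = 50, seed = 1)
  expect_lt(abs(fit$k), 1e-6)
  expect_lt(abs(fit$b - 0.2), 1e-6)
  expect_equal(fit$s, fit$b * (mu + fit$k), tolerance = 1e-12)
  # adding the catabolic parameter never increases the weighted RSS
  expect_gte(fit$delta_rss, 0)
})

test_that("a catabolic rate equal to mu is recovered from noisy data", {
  mu <- log(2) / 12
  hits <- 0L
  for (s in 1:10) {
    cfg <- study_config(seed = s, catabolic_rate_h = mu)
    fit <- fit_turnover(gen_decay_experiment(cfg), mu, n_boot = 300, seed = s)
    hits <- hits + (fit$ci_k[1] <= mu && mu <= fit$ci_k[2])
  }
  expect_gte(hits, 8L)
})

test_that("the k >= 0 fit never beats its nested k = 0 fit on k = 0 data", {
  for (s in 1:5) {
    cfg <- study_config(seed = s)
    fit <- fit_turnover(gen_decay_experiment(cfg), log(2) / 12,
                        n_boot = 50, seed = s)
    expect_gte(fit$delta_rss, 0)
    expect_gte(fit$b, 0)
    expect_gte(fit$k, 0)
  }
})

test_that("net catabolism verdicts follow the one-sided comparison", {
  mu <- log(2) / 12
  times <- c(0, 4, 8, 12, 16, 24, 32)
  # measured identical to predicted: no catabolism
  d <- noiseless_decay(times, b = 0, mu = mu, k = 0)
  expect_identical(net_catabolism_test(d, 12)$verdict, "no net catabolism")
  # plateau above the prediction at late times: still no catabolism
  dplat <- noiseless_decay(times, b = 0.25, mu = mu, k = 0)
  expect_identical(net_catabolism_test(dplat, 12)$verdict, "no net catabolism")
  # measured at half the prediction with tight SEM: detected
  dhalf <- do.call(rbind, lapply(1:3, function(r) {
    x <- noiseless_decay(times, b = 0, mu = mu, k = 0)
    x$replicate <- r
    x$signal <- x$signal * 0.5 * (1 + 0.002 * (r - 2))
    x$signal[x$time_h == 0] <- x$signal[x$time_h == 0] / 0.5
    x
  }))
  res <- net_catabolism_test(dhalf, 12)
  expect_identical(res$verdict, "net catabolism detected")
  expect_true(any(res$table$significantly_below))
})

test_that("false detection of catabolism is controlled on k = 0 data", {
  false_pos <- 0L
  for (s in 1:100) {
    cfg <- study_config(seed = s)
    ds <- as_decay_series(gen_decay_experiment(cfg))
    false_pos <- false_pos + net_catabolism_test(ds, 12)$detected
  }
  expect_lte(false_pos, 10L)
})

test_that("the combined decay report reproduces the turnover analysis", {
  cfg <- study_config(seed = 6L)
  rep_wt <- decay_report(gen_decay_experiment(cfg), gen_growth_curve(cfg),
                         n_boot = 200, seed = 6)
  expect_identical(rep_wt$verdict, "no net catabolism")
  expect_true(rep_wt$fit$ci_k[1] <= 1e-9)
  # a genotype with identical storage kinetics gives the same verdict
  cfg_ko <- study_config(seed = 61L)
  rep_ko <- decay_report(gen_decay_experiment(cfg_ko), gen_growth_curve(cfg_ko),
                         n_boot = 200, seed = 61)
  expect_identical(rep_ko$verdict, rep_wt$verdict)
  # strong catabolism flips the verdict
  cfg_k <- study_config(seed = 6L, catabolic_rate_h = 0.1)
  rep_k <- decay_report(gen_decay_experiment(cfg_k), gen_growth_curve(cfg_k),
                        n_boot = 200, seed = 6)
  expect_identical(rep_k$verdict, "net catabolism detected")
})
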