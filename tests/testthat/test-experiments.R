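test_that("drive normalization maps the observed range to the unit interval", {
  set.seed(61)
  tr <- two_neuron_sim(n_windows = 300, c = 0.3)
  trn <- normalize_drive(tr)
  zn <- attr(trn, "z_normalization")
  for (i in 1:2) {
    z <- trn$Z[trn$neuron == i]
    expect_equal(range(z), c(0, 1))
    # threshold maps consistently: spike set unchanged
    expect_identical(as.integer(z >= zn[i, "theta"]),
                     tr$H[tr$neuron == i])
  }
})

test_that("identical configuration and seed give identical tables", {
  a <- run_two_neuron_sweep(c_grid = 0.3, p_grid = c(0.1, 1), n_windows = 200,
                            n_repeats = 2, gt_windows = 500, seed = 99)
  b <- run_two_neuron_sweep(c_grid = 0.3, p_grid = c(0.1, 1), n_windows = 200,
                            n_repeats = 2, gt_windows = 500, seed = 99)
  expect_identical(a, b)
  d <- run_two_neuron_sweep(c_grid = 0.3, p_grid = c(0.1, 1), n_windows = 200,
                            n_repeats = 2, gt_windows = 500, seed = 100)
  expect_false(identical(a$mean_beta, d$mean_beta))
})

test_that("the two-neuron sweep reproduces its boundary behaviour", {
  sw <- run_two_neuron_sweep(c_grid = c(0.01, 0.5), p_grid = c(0.1, 1),
                             n_windows = 1200, n_repeats = 4,
                             gt_windows = 6000, seed = 5)
  expect_true(all(c("c", "p", "method", "neuron", "mean_beta", "sd_beta",
                    "bias") %in% names(sw)))
  # the full-range piecewise-constant column equals the observed dependence
  for (cc in c(0.01, 0.5)) for (i in 1:2) {
    s1 <- sw[sw$c == cc & sw$method == "sde0" & sw$neuron == i & sw$p == 1, ]
    od <- sw[sw$c == cc & sw$method == "od" & sw$neuron == i, ]
    expect_equal(s1$mean_beta, od$mean_beta, tolerance = 1e-12)
  }
  # unconfounded row: observed dependence agrees with the discontinuity
  s_unc <- sw[sw$c == 0.01 & sw$method == "sde0" & sw$p == 0.1, ]
  o_unc <- sw[sw$c == 0.01 & sw$method == "od", ]
  expect_lt(max(abs(s_unc$mean_beta - o_unc$mean_beta) /
                  pmax(o_unc$sd_beta, 1e-9)), 3)
})

test_that("the weight sweep records firing regime and flags silent cells", {
  ws <- run_weight_sweep(w_grid = c(2, 10, 16), p = 0.1, n_windows = 1000,
                         gt_windows = 3000, seed = 5)
  expect_equal(nrow(ws), 2 * 9)
  # silent cells (w = 2 at this operating point) are NA-flagged, not fatal
  silent <- ws$w1 == 2 & ws$neuron == 1
  expect_true(all(!is.finite(ws$beta_sde[silent])  |
                    ws$rate[silent] < 0.5))
  live <- is.finite(ws$rel_error_sde) & ws$rate > 1
  expect_gt(sum(live), 4)
  expect_true(all(ws$rate >= 0))
  expect_true(all(ws$grad_angle_sde[live] >= 0 &
                    ws$grad_angle_sde[live] <= 180))
})

test_that("discontinuity error tracks the firing regime across the sweep", {
  ws <- run_weight_sweep(w_grid = c(8, 11, 14, 17), p = 0.05,
                         n_windows = 1500, n_repeats = 3, gt_windows = 6000,
                         seed = 11)
  ok <- is.finite(ws$rel_error_sde) & is.finite(ws$isi_cv) & ws$rate > 1
  d <- ws[ok, ]
  med_cv <- median(d$isi_cv)
  hi_cv <- median(d$rel_error_sde[d$isi_cv > med_cv])
  lo_cv <- median(d$rel_error_sde[d$isi_cv <= med_cv])
  expect_lt(hi_cv, lo_cv)   # more irregular firing, better estimates
  med_rate <- median(d$rate)
  lo_rate <- median(d$rel_error_sde[d$rate <= med_rate])
  hi_rate <- median(d$rel_error_sde[d$rate > med_rate])
  expect_lt(lo_rate, hi_rate)  # sparser firing, better estimates
})

test_that("the wide-network sweep separates the estimators under confounding", {
  res <- run_wide_network(N_grid = 8, c_grid = c(0.01, 0.9), p = 0.05,
                          n_windows = 1200, n_repeats = 2, gt_windows = 8000,
                          seed = 3)
  expect_equal(nrow(res), 4)
  od <- res[res$method == "od", ]
  sde <- res[res$method == "sde0", ]
  # low correlation: the naive estimator is at least as accurate
  expect_lte(od$mse[od$c == 0.01], sde$mse[sde$c == 0.01] * 1.5)
  # high correlation blows up the naive estimator far more
  expect_gt(od$mse[od$c == 0.9] / od$mse[od$c == 0.01],
            5 * sde$mse[sde$c == 0.9] / sde$mse[sde$c == 0.01])
})

test_that("the deep network keeps the discontinuity estimator near truth", {
  dp <- run_deep_network(N = 6, c = 0.5, p_grid = c(0.05, 0.1),
                         n_windows = 2500, gt_windows = 10000, seed = 5)
  expect_setequal(unique(dp$condition), c("correlated", "uncorrelated"))
  od_cor <- dp[dp$method == "od" & dp$condition == "correlated", ]
  od_unc <- dp[dp$method == "od" & dp$condition == "uncorrelated", ]
  # the naive estimator degrades sharply once inputs are correlated
  expect_gt(mean(abs(od_cor$beta_hat - od_cor$beta_true)),
            2 * mean(abs(od_unc$beta_hat - od_unc$beta_true)))
  # the discontinuity estimator beats it for most first-layer neurons
  sde_cor <- dp[dp$method == "sde0" & dp$condition == "correlated" &
                  dp$p == 0.05, ]
  err_sde <- abs(sde_cor$beta_hat - sde_cor$beta_true)
  err_od <- abs(od_cor$beta_hat - od_cor$beta_true)
  expect_gt(mean(err_sde < err_od, na.rm = TRUE), 0.5)
})

test_that("the refractory sweep runs across its grid, including zero", {
  rs <- run_refractory_sweep(refractory_grid = c(0, 0.001, 0.003, 0.005),
                             w_grid = c(10, 14), p = 0.1, n_windows = 800,
                             gt_windows = 2500, seed = 5)
  expect_equal(nrow(rs), 4)
  expect_true(all(is.finite(rs$median_rel_error)))
  # error comparable across refractory settings (within a factor of two
  # of each other, excluding the degenerate zero row if it differs)
  meds <- rs$median_rel_error[rs$refractory_ms > 0]
  expect_lt(max(meds) / min(meds), 2)
})

test_that("run_experiment writes its table and resolved configuration", {
  out <- tempfile()
  cfg <- experiment_config("two_neuron_sweep", n_windows = 150, n_repeats = 1,
                           seed = 4, c_grid = 0.2, p_grid = c(0.2, 1),
                           gt_windows = 400)
  run_experiment(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "two_neuron_sweep.csv")))
  expect_true(file.exists(file.path(out, "config.json")))
  cfg_back <- jsonlite::read_json(file.path(out, "config.json"))
  expect_equal(cfg_back$seed, 4)
  unlink(out, recursive = TRUE)
})

test_that("the command-line driver simulates and estimates end to end", {
  cli <- system.file("cli", "spikecause.R", package = "spikecause")
  expect_true(nzchar(cli))
  out <- tempfile()
  res <- system2("Rscript", c(cli, "simulate", "--seed", "3", "--out", out,
                              "--windows", "120"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "trials.csv")))
  out2 <- tempfile()
  res2 <- system2("Rscript", c(cli, "estimate", "--trials",
                               file.path(out, "trials.csv"), "--p", "0.3",
                               "--out", out2),
                  stdout = TRUE, stderr = TRUE)
  est <- utils::read.csv(file.path(out2, "estimates.csv"))
  expect_true(all(c("neuron", "method", "beta") %in% names(est)))
  unlink(c(out, out2), recursive = TRUE)
})
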