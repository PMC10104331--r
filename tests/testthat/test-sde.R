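test_that("observed dependence is the spike/no-spike mean difference", {
  tr <- manual_trials(Z = c(1.2, 1.1, 0.8), H = c(1, 1, 0), R = c(2, 2, 1))
  expect_equal(as.numeric(observed_dependence(tr, 1)), 1.0)
  tr2 <- manual_trials(Z = c(1.2, 0.8, 1.4, 0.5), H = c(1, 0, 1, 0),
                       R = rep(3, 4))
  expect_equal(as.numeric(observed_dependence(tr2, 1)), 0)
  tr3 <- manual_trials(Z = c(1.2, 1.3), H = c(1, 1), R = c(1, 2))
  expect_error(observed_dependence(tr3, 1), "undefined")
})

test_that("observed dependence reproduces a confounded toy joint exactly", {
  # binary confounder H2 drives both H1 and R; the true effect of H1 is zero.
  # joint: P(H2=1)=0.5, P(H1=1|H2)= 0.2 + 0.6 H2, R = 1 + 2 H2.
  p_joint <- c(h2_0_h1_0 = 0.5 * 0.8, h2_0_h1_1 = 0.5 * 0.2,
               h2_1_h1_0 = 0.5 * 0.4, h2_1_h1_1 = 0.5 * 0.6)
  r_of <- c(h2_0_h1_0 = 1, h2_0_h1_1 = 1, h2_1_h1_0 = 3, h2_1_h1_1 = 3)
  h1_of <- c(0, 1, 0, 1)
  # brute-force enumeration of E(R | H1)
  e_r_h1 <- function(h) {
    w <- p_joint[h1_of == h]
    sum(w * r_of[h1_of == h]) / sum(w)
  }
  od_expected <- e_r_h1(1) - e_r_h1(0)
  # build a finite table whose empirical frequencies equal the joint
  n_per <- round(p_joint * 1000)
  tr <- manual_trials(
    Z = rep(ifelse(h1_of == 1, 1.5, 0.5), n_per),
    H = rep(h1_of, n_per),
    R = rep(r_of, n_per))
  expect_equal(as.numeric(observed_dependence(tr, 1)), od_expected)
  expect_gt(abs(od_expected), 0.4)  # naive estimate is far from the true 0
})

test_that("a two-point window yields the mean jump", {
  tr <- manual_trials(Z = c(0.95, 1.05), H = c(0, 1), R = c(1, 3))
  f <- sde_fit(tr, 1, p = 0.1, theta = 1)
  expect_equal(f$beta, 2)
  expect_equal(unname(coef(f)["gamma"]), 1)
})

test_that("a trial exactly at threshold counts as a spike trial", {
  tr <- manual_trials(Z = c(0.95, 1.0), H = c(0, 1), R = c(1, 5))
  f <- sde_fit(tr, 1, p = 0.1, theta = 1)
  expect_equal(f$beta, 4)
  expect_equal(f$n_above, 1L)
})

test_that("a full-range window reduces bitwise to the observed dependence", {
  set.seed(8)
  tr <- two_neuron_sim(n_windows = 600, c = 0.4)
  for (i in 1:2) {
    od <- as.numeric(observed_dependence(tr, i))
    f <- sde_fit(tr, i, p = Inf, theta = 1, order = 0)
    expect_identical(f$beta, od)
  }
})

test_that("the one-sided window uses all spike trials above threshold", {
  tr <- manual_trials(Z = c(0.95, 1.05, 1.5, 2.5), H = c(0, 1, 1, 1),
                      R = c(1, 2, 4, 9))
  sym <- sde_fit(tr, 1, p = 0.1, theta = 1)
  one <- sde_fit(tr, 1, p = 0.1, theta = 1, side = "one_sided")
  expect_equal(sym$beta, 1)           # only Z = 1.05 above
  expect_equal(one$beta, mean(c(2, 4, 9)) - 1)
  expect_equal(one$n_above, 3L)
})

test_that("the piecewise-linear fit recovers a noiseless generating model", {
  set.seed(12)
  theta <- 1
  gamma <- 2; beta <- 5; a_r <- 1.5; a_l <- -0.7
  Z <- runif(200, 0.5, 1.5)
  H <- as.integer(Z >= theta)
  R <- gamma + beta * H + (a_r * H + a_l * (1 - H)) * (Z - theta)
  tr <- manual_trials(Z, H, R)
  f <- sde_fit(tr, 1, p = 0.5, theta = theta, order = 1)
  expect_equal(unname(coef(f)), c(gamma, beta, a_r, a_l), tolerance = 1e-10)
  expect_lt(max(abs(residuals(f))), 1e-10)
  expect_equal(unname(predict(f, data.frame(Z = 1, H = 1))), gamma + beta,
               tolerance = 1e-10)
})

test_that("degenerate designs raise informative errors", {
  # no trials above threshold
  tr <- manual_trials(Z = c(0.9, 0.95), H = c(0, 0), R = c(1, 1))
  expect_error(sde_fit(tr, 1, p = 0.2, theta = 1), "above")
  # both spike classes required for the linear model
  tr2 <- manual_trials(Z = c(1.01, 1.02, 1.03, 1.04), H = rep(1L, 4),
                       R = 1:4)
  expect_error(sde_fit(tr2, 1, p = 0.1, theta = 1, order = 1))
  # collinear in-window design (single Z value per side)
  tr3 <- manual_trials(Z = rep(c(0.95, 1.05), 5), H = rep(c(0, 1), 5),
                       R = rnorm(10))
  expect_error(sde_fit(tr3, 1, p = 0.1, theta = 1, order = 1),
               "rank deficient")
  expect_error(sde_fit(tr, 1, p = -1, theta = 1), "positive")
})

test_that("estimators agree with ground truth in the unconfounded network", {
  set.seed(21)
  pars <- lif_params()
  ns <- noise_spec(c = 0, n_neurons = 2)
  net <- network_weights(c(10, 10))
  rw <- reward_spec("quadratic2")
  gt <- ground_truth_effect(pars, ns, net, rw, 30000)
  est <- replicate(6, {
    tr <- simulate_run(pars, ns, net, rw, 2000)
    trn <- normalize_drive(tr)
    zn <- attr(trn, "z_normalization")
    c(od = as.numeric(observed_dependence(tr, 1)),
      sde0 = sde_fit(trn, 1, p = 0.1, theta = zn[1, "theta"])$beta,
      sde1 = sde_fit(trn, 1, p = 0.3, theta = zn[1, "theta"], order = 1)$beta)
  })
  for (m in rownames(est)) {
    sdm <- sd(est[m, ])
    expect_lt(abs(mean(est[m, ]) - gt$beta_true[1]), 2 * sdm)
  }
})

test_that("ground-truth standard errors scale as one over root n", {
  set.seed(31)
  pars <- lif_params()
  ns <- noise_spec(c = 0.5, n_neurons = 2)  # forced to 0 internally
  net <- network_weights(c(10, 10))
  rw <- reward_spec("quadratic2")
  g1 <- ground_truth_effect(pars, ns, net, rw, 3000)
  g2 <- ground_truth_effect(pars, ns, net, rw, 12000)
  expect_equal(g1$se[1] / g2$se[1], 2, tolerance = 0.35)
})

test_that("a reward blind to a neuron yields a null ground-truth effect", {
  set.seed(41)
  pars <- lif_params()
  ns <- noise_spec(c = 0, n_neurons = 2)
  net <- network_weights(c(10, 10))
  rw <- reward_spec("linear_readout", U = c(0, 1), Y_target = 0.1)
  gt <- ground_truth_effect(pars, ns, net, rw, 20000)
  expect_lt(abs(gt$beta_true[1]), 2 * gt$se[1])
  expect_gt(abs(gt$beta_true[2]), 2 * gt$se[2])
})

test_that("effect metrics behave on canonical vectors", {
  m <- effect_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$mse, 0)
  expect_equal(m$alignment_deg, 0)
  m2 <- effect_metrics(c(1, 0), c(0, 1))
  expect_equal(m2$alignment_deg, 90)
  b <- c(1, -2, 0.5)
  m3 <- effect_metrics(2 * b, b)
  expect_equal(m3$alignment_deg, 0, tolerance = 1e-10)
  expect_equal(m3$mse, mean(b^2))
  expect_error(effect_metrics(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(effect_metrics(1:2, 1:3), "length")
})

test_that("estimate_effects tabulates all methods and flags failures", {
  set.seed(51)
  tr <- two_neuron_sim(n_windows = 600, c = 0.2)
  tab <- estimate_effects(tr, p = 0.3, theta = 1)
  expect_setequal(unique(tab$method), c("od", "sde0", "sde1"))
  expect_equal(nrow(tab), 6)
  expect_true(all(is.finite(tab$beta)))
  # a never-spiking neuron is reported as NA, not an error
  tr_silent <- manual_trials(Z = runif(50, 0, 0.5), H = 0L, R = rnorm(50))
  tab2 <- estimate_effects(tr_silent, p = 0.2, theta = 1)
  expect_true(all(is.na(tab2$beta)))
})
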