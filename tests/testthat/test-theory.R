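test_that("the analytic trace jump has its closed-form values and limits", {
  expect_equal(delta_s_analytic(0.05, 0.02), 18.3583, tolerance = 1e-4)
  # T -> 0 limit is 1/tau_s
  expect_equal(delta_s_analytic(1e-8, 0.02), 50, tolerance = 1e-4)
  # strictly decreasing in both arguments, bounded by 1/tau_s
  Ts <- seq(0.01, 0.1, length.out = 20)
  expect_true(all(diff(delta_s_analytic(Ts, 0.02)) < 0))
  taus <- seq(0.01, 0.1, length.out = 20)
  expect_true(all(diff(delta_s_analytic(0.05, taus)) < 0))
  expect_true(all(delta_s_analytic(Ts, 0.02) <= 1 / 0.02))
  expect_true(all(delta_s_analytic(Ts, 0.02) > 0))
  expect_error(delta_s_analytic(-0.1, 0.02), "positive")
  expect_error(delta_s_analytic(0.05, 0), "positive")
})

test_that("the empirical offset recovers an exact translation", {
  set.seed(3)
  s0 <- rgamma(4000, shape = 2, rate = 1)
  delta <- 1.7
  S <- c(s0, s0 + delta)
  H <- rep(c(0L, 1L), each = 4000)
  est <- delta_s_empirical(S, H)
  expect_equal(as.numeric(est), delta, tolerance = 1e-6)
  expect_equal(attr(est, "mean_diff"), delta, tolerance = 1e-6)
  # identical distributions give zero
  est0 <- delta_s_empirical(c(s0, s0), H)
  expect_equal(as.numeric(est0), 0, tolerance = 1e-9)
  # pure location statistic: shifting everything changes nothing
  est_sh <- delta_s_empirical(S + 100, H)
  expect_equal(as.numeric(est_sh), as.numeric(est), tolerance = 1e-9)
  expect_error(delta_s_empirical(s0, rep(0L, 4000)), "insufficient")
})

test_that("spiking windows shift the trace by the analytic jump", {
  set.seed(17)
  tr <- simulate_poisson_trace(rate = 1.5, T = 0.05, tau_s = 0.02,
                               n_windows = 60000)
  de <- delta_s_empirical(tr$S, tr$H)
  da <- delta_s_analytic(0.05, 0.02)
  # mean difference carries the spike-multiplicity factor lambda/(1-e^-lambda)
  lam <- 1.5 * 0.05
  expect_equal(attr(de, "mean_diff") / (da * lam / (1 - exp(-lam))), 1,
               tolerance = 0.05)
})

test_that("the trace offset is rate independent in the sparse regime", {
  offs <- vapply(c(5, 20, 50), function(r) {
    set.seed(100 + r)
    tr <- simulate_poisson_trace(r, T = 0.002, tau_s = 0.02,
                                 n_windows = 150000)
    as.numeric(delta_s_empirical(tr$S, tr$H))
  }, numeric(1))
  expect_lt(max(offs) / min(offs), 1.10)
})

test_that("the QQ translation model holds on simulated trains", {
  set.seed(23)
  tr <- simulate_poisson_trace(rate = 20, T = 0.005, tau_s = 0.1,
                               n_windows = 80000)
  q <- seq(0.1, 0.9, by = 0.1)
  q1 <- quantile(tr$S[tr$H == 1], q); q0 <- quantile(tr$S[tr$H == 0], q)
  fit <- lm(q1 ~ q0)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)  # unit slope
  expect_lt(max(abs(residuals(fit))), 0.05 * diff(range(q0)))
})

test_that("the finite-difference reward operator is exact for linear rewards", {
  U <- c(2, -3, 0.5)
  f <- function(s) sum(U * s)
  for (d in c(0.01, 0.5, 5)) {
    expect_equal(finite_difference_reward(f, c(1, 1, 1), 2, d), U[2])
  }
  expect_error(finite_difference_reward(f, c(1, 1, 1), 2, 0), "positive")
})

test_that("the difference quotient converges to the analytic partial", {
  spec <- reward_spec("quadratic2")
  f <- as_reward_fn(spec)
  s <- c(0.1, 0.15)
  true_d1 <- 2 * (spec$a * s[1] + spec$b * s[2] + spec$b * s[2]^2 + spec$x_r) *
    spec$a
  errs <- vapply(c(0.1, 0.01, 0.001), function(d)
    abs(finite_difference_reward(f, s, 1, d) - true_d1), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / abs(true_d1), 0.01)
  expect_equal(finite_difference_reward(f, s, 1, 1e-7), true_d1,
               tolerance = 1e-4)
})

test_that("the validation grid matches theory and records failures", {
  set.seed(29)
  g <- validate_delta_s_grid(n_grid = 3, rate = 1, n_windows = 30000)
  expect_equal(nrow(g), 9)
  expect_true(all(is.na(g$error)))
  expect_true(all(g$ratio > 0.85 & g$ratio < 1.15))
  # zero rate: no spiking windows, failure recorded per cell, not fatal
  g0 <- validate_delta_s_grid(n_grid = 2, rate = 0, n_windows = 100)
  expect_true(all(!is.na(g0$error)))
  expect_true(all(is.na(g0$ratio)))
})

test_that("the trace jump converts reward differences into causal effects", {
  # linear readout: beta ~ Delta_s * E(D_i R | no spike), with the jump in
  # the units of the simulator's unit-amplitude kernel
  set.seed(37)
  pars <- lif_params()
  ns <- noise_spec(c = 0, n_neurons = 2)
  net <- network_weights(c(10, 10))
  U <- c(1.5, -1)
  rw <- reward_spec("linear_readout", U = U, Y_target = 0.1)
  gt <- ground_truth_effect(pars, ns, net, rw, 30000)
  tr <- simulate_run(pars, ns, net, rw, 4000)
  f <- as_reward_fn(rw)
  ds <- pars$tau_s * delta_s_analytic(pars$T, pars$tau_s) * pars$syn_jump
  h0 <- tr$trial[tr$neuron == 1 & tr$H == 0]
  S1 <- tr$S[tr$neuron == 1][h0]; S2 <- tr$S[tr$neuron == 2][h0]
  dir_ <- vapply(seq_along(S1), function(k)
    finite_difference_reward(f, c(S1[k], S2[k]), 1, ds), numeric(1))
  beta_fd <- ds * mean(dir_)
  # multiplicity correction: the reference effect includes multi-spike windows
  lam <- -log(1 - mean(tr$H[tr$neuron == 1]))
  mult <- lam / (1 - exp(-lam))
  expect_lt(abs(beta_fd * mult - gt$beta_true[1]),
            2 * gt$se[1] + 0.15 * abs(gt$beta_true[1]))
})
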