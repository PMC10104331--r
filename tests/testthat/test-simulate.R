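test_that("a silent network produces no spikes and a decaying trace", {
  set.seed(1)
  pars <- lif_params()
  tr <- simulate_run(pars, noise_spec(x_dc = 0, sigma = 0, n_neurons = 2),
                     network_weights(c(0, 0)), reward_spec("quadratic2"),
                     n_windows = 10, s0 = c(1, 1))
  expect_true(all(tr$H == 0))
  expect_true(all(tr$Z == 0))
  # with zero spikes, S decays by exp(-kT/tau_s) from its initial value
  s1 <- tr$S[tr$neuron == 1]
  expect_equal(s1, exp(-(1:10) * pars$T / pars$tau_s), tolerance = 1e-12)
})

test_that("strong suprathreshold drive spikes in every window", {
  set.seed(1)
  tr <- simulate_run(lif_params(), noise_spec(x_dc = 20, sigma = 0.01,
                                              n_neurons = 1),
                     network_weights(10),
                     reward_spec("linear_readout", U = 1, Y_target = 0), 50)
  expect_true(all(tr$H == 1))
})

test_that("the spike indicator equals the threshold crossing of the drive", {
  pars <- lif_params()
  for (cc in c(0, 0.5, 0.9)) {
    set.seed(100 + round(100 * cc))
    tr <- two_neuron_sim(n_windows = 400, c = cc)
    expect_identical(tr$H, as.integer(tr$Z >= pars$theta))
  }
  # also holds in a two-layer network
  set.seed(7)
  V <- matrix(rnorm(9, 50, 20), 3, 3)
  tr <- simulate_run(pars, noise_spec(x_dc = 48, c = 0.5, n_neurons = 3),
                     network_weights(rep(1, 3), V = V, w2 = rep(0.1, 3)),
                     reward_spec("deep_readout", U = rep(1, 3),
                                 Y_target = 0.02), 300)
  expect_identical(tr$H, as.integer(tr$Z >= pars$theta))
})

test_that("drive and membrane agree within a window until the first spike", {
  set.seed(3)
  pars <- lif_params()
  tr <- two_neuron_sim(n_windows = 40, c = 0.3, traces = TRUE)
  v <- attr(tr, "v_trace"); u <- attr(tr, "u_trace")
  spw <- pars$steps_per_window
  for (wdx in seq_len(40)) {
    rows <- ((wdx - 1) * spw + 1):(wdx * spw)
    for (i in 1:2) {
      cross <- which(u[rows, i] >= pars$theta)[1]
      upto <- if (is.na(cross)) length(rows) else cross - 1L
      if (upto > 0)
        expect_equal(u[rows[1:upto], i], v[rows[1:upto], i], tolerance = 1e-12)
      # membrane never sits above threshold (reset at crossing)
      expect_true(all(v[rows, i] < pars$theta + 1e-9))
    }
  }
})

test_that("halving the integration step leaves window statistics consistent", {
  run_stats <- function(dt) {
    set.seed(11)
    tr <- simulate_run(lif_params(dt = dt),
                       noise_spec(x_dc = 2.5, c = 0, n_neurons = 1),
                       network_weights(10),
                       reward_spec("linear_readout", U = 1, Y_target = 0), 3000)
    c(pH = mean(tr$H), mS = mean(tr$S), mZ = mean(tr$Z))
  }
  a <- run_stats(0.001)
  b <- run_stats(0.0005)
  # Euler convergence: distributional change on refinement is small
  expect_lt(abs(a["pH"] - b["pH"]), 0.04)
  expect_lt(abs(a["mS"] - b["mS"]) / b["mS"], 0.15)
  expect_lt(abs(a["mZ"] - b["mZ"]) / b["mZ"], 0.05)
})

test_that("numerical divergence is reported with the offending step", {
  # dt far above the stability limit of the leak makes Euler blow up
  pars <- lif_params(g_L = 50, dt = 1, T = 200, refractory = 0)
  expect_error(
    simulate_run(pars, noise_spec(x_dc = 1, sigma = 1, n_neurons = 1),
                 network_weights(5),
                 reward_spec("linear_readout", U = 1, Y_target = 0), 1),
    "diverged")
})

test_that("synaptic state carries across window boundaries", {
  set.seed(5)
  pars <- lif_params()
  tr <- two_neuron_sim(n_windows = 200, c = 0)
  s <- tr$S[tr$neuron == 1]
  h <- tr$H[tr$neuron == 1]
  # windows without a spike start from the previous window's trace:
  # S_k <= S_{k-1} (pure decay plus nothing) and >= decayed lower bound
  no_spike <- which(h == 0)[-1]
  no_spike <- no_spike[no_spike > 1]
  dec <- exp(-pars$T / pars$tau_s)
  expect_true(all(s[no_spike] <= s[no_spike - 1] + 1e-12))
  expect_true(all(abs(s[no_spike] - s[no_spike - 1] * dec) < 1e-9))
})

test_that("trial tables survive a CSV round trip and reject missing data", {
  set.seed(2)
  tr <- two_neuron_sim(n_windows = 20)
  f <- tempfile(fileext = ".csv")
  write_trials(tr, f)
  back <- read_trials(f)
  expect_equal(back$Z, tr$Z)
  expect_equal(back$R, tr$R)
  expect_equal(attr(back, "theta"), attr(tr, "theta"))
  txt <- readLines(f)
  expect_true(any(grepl("^# ", txt)))  # units header present
  # a missing value is refused on read
  txt[8] <- sub("^([^,]*,[^,]*),[^,]*", "\\1,NA", txt[8])
  writeLines(txt, f)
  expect_error(read_trials(f), "missing")
  unlink(f)
})
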