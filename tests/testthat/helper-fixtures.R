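# shared fixtures: small, fast configurations used across test files

pars0 <- function(...) lif_params(...)

two_neuron_sim <- function(n_windows = 500, c = 0, w = c(10, 10),
                           x_dc = 2.5, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_run(lif_params(), noise_spec(x_dc = x_dc, c = c, n_neurons = 2),
               network_weights(w), reward_spec("quadratic2"), n_windows, ...)
}

# deterministic trial table built by hand (no simulation)
manual_trials <- function(Z, H, R, neuron = 1, theta = 1) {
  out <- data.frame(trial = seq_along(Z), neuron = neuron,
                    Z = Z, H = H, S = 0, X = 0, R = R)
  attr(out, "theta") <- theta
  class(out) <- c("spike_trials", "data.frame")
  out
}
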