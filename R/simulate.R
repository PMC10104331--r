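#' Simulate an LIF network and aggregate it into trial windows
#'
#' Runs the network continuously with Euler-Maruyama integration and segments
#' the run into `n_windows` windows of length `params$T`.  Within each window
#' the input drive `u` is re-initialized to the membrane potential `v` at the
#' window start and integrated without reset, so its maximum `Z` separates
#' marginally sub-threshold from marginally super-threshold trials; the spike
#' indicator satisfies `H = 1` exactly when `Z >= theta`.  Membrane potential
#' and synaptic traces carry over across window boundaries (residual
#' refractory state is cleared at each boundary so that `u` and `v` start
#' every window aligned).  Reward is computed at the end of each window from
#' the vector of synaptic traces `S`.
#'
#' Uses the current R random-number stream; call [set.seed()] first for
#' reproducibility.
#'
#' @param params A [lif_params()].
#' @param noise A [noise_spec()]; `noise$n_neurons` must equal the
#'   first-layer width of `network`.
#' @param network A [network_weights()].
#' @param reward A [reward_spec()].
#' @param n_windows Number of trial windows to simulate.
#' @param v0,s0 Optional initial membrane potentials / synaptic traces
#'   (length = total neuron count; default 0).
#' @param traces If `TRUE`, also return the full per-step `v`, `u`, `s`
#'   traces (memory grows with `n_windows`; intended for short runs).
#' @param record_spikes If `TRUE`, attach the spike times (s, per neuron) as
#'   the `spike_times` attribute, e.g. for inter-spike-interval statistics.
#' @return A `spike_trials` data frame with one row per (trial, neuron) and
#'   columns `trial`, `neuron`, `Z`, `H`, `S`, `X`, `R`.  Attributes carry
#'   the resolved parameter objects, the final state (`v_final`, `s_final`)
#'   and, if requested, the trace matrices.
#' @examples
#' set.seed(1)
#' tr <- simulate_run(lif_params(), noise_spec(c = 0.5, n_neurons = 2),
#'                    network_weights(c(10, 10)), reward_spec("quadratic2"),
#'                    n_windows = 20)
#' head(tr)
#' @export
simulate_run <- function(params, noise, network, reward, n_windows,
                         v0 = NULL, s0 = NULL, traces = FALSE,
                         record_spikes = FALSE) {
  stopifnot(inherits(params, "lif_params"), inherits(noise, "noise_spec"),
            inherits(network, "network_weights"),
            inherits(reward, "reward_spec"))
  if (n_windows < 1) stop("'n_windows' must be at least 1", call. = FALSE)
  if (noise$n_neurons != network$n1)
    stop("noise_spec covers ", noise$n_neurons,
         " neurons but the first layer has ", network$n1, call. = FALSE)
  n <- network$n
  if (is.null(v0)) v0 <- rep(0, n)
  if (is.null(s0)) s0 <- rep(0, n)
  stopifnot(length(v0) == n, length(s0) == n)

  k <- lif_kernel(as.integer(n_windows), params$steps_per_window, params$dt,
                  params$g_L, params$theta, params$v_r, params$ref_steps,
                  params$tau_s, params$syn_jump,
                  network$w1, noise$x_dc, noise$sigma, noise$c,
                  network$V, network$w2, noise$sigma2,
                  as.numeric(v0), as.numeric(s0), traces, record_spikes)

  R <- eval_reward(reward, k$S, network$n1)
  out <- data.frame(
    trial = rep(seq_len(n_windows), times = n),
    neuron = rep(seq_len(n), each = n_windows),
    Z = as.vector(k$Z), H = as.vector(k$H), S = as.vector(k$S),
    X = as.vector(k$X), R = rep(R, times = n))
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  attr(out, "network") <- network
  attr(out, "reward") <- reward
  attr(out, "theta") <- params$theta
  attr(out, "v_final") <- k$v_final
  attr(out, "s_final") <- k$s_final
  if (traces) {
    attr(out, "v_trace") <- k$v_trace
    attr(out, "u_trace") <- k$u_trace
    attr(out, "s_trace") <- k$s_trace
  }
  if (record_spikes) attr(out, "spike_times") <- k$spike_times
  class(out) <- c("spike_trials", "data.frame")
  out
}

#' @export
print.spike_trials <- function(x, ...) {
  nt <- max(x$trial); nn <- max(x$neuron)
  cat(sprintf("Trial summaries: %d windows x %d neurons\n", nt, nn))
  rates <- tapply(x$H, x$neuron, mean)
  cat("  P(spike per window):", paste(signif(rates, 3), collapse = ", "), "\n")
  cat(sprintf("  reward: mean %.4g, sd %.4g\n", mean(x$R[x$neuron == 1]),
              stats::sd(x$R[x$neuron == 1])))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
summary.spike_trials <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(object, object$neuron), function(d) {
    data.frame(neuron = d$neuron[1], p_spike = mean(d$H),
               mean_Z = mean(d$Z), mean_S = mean(d$S), mean_X = mean(d$X))
  }))
  rownames(agg) <- NULL
  agg
}

#' Write / read trial-summary tables
#'
#' CSV with columns `trial, neuron, Z, H, S, X, R`, one row per
#' (trial, neuron), preceded by comment lines recording units and the spike
#' threshold.  `read_trials()` restores the `spike_trials` class and the
#' `theta` attribute.
#'
#' @param trials A `spike_trials` data frame (or compatible).
#' @param file Path to the CSV file.
#' @return `write_trials()` returns `file` invisibly; `read_trials()` returns
#'   a `spike_trials` data frame.
#' @export
write_trials <- function(trials, file) {
  theta <- attr(trials, "theta")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "# spikecause trial summaries; times in s, rates in 1/s",
    "# Z: max input drive; H: spike indicator; S: end-of-window synaptic trace;",
    "# X: time-averaged input; R: end-of-window reward",
    sprintf("# theta: %.17g", if (is.null(theta)) NA_real_ else theta)), con)
  utils::write.csv(as.data.frame(trials)[, c("trial", "neuron", "Z", "H", "S", "X", "R")],
                   con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  hdr <- readLines(file, n = 10)
  theta_line <- grep("^# theta:", hdr, value = TRUE)
  theta <- if (length(theta_line)) as.numeric(sub("^# theta:", "", theta_line[1])) else NA_real_
  out <- utils::read.csv(file, comment.char = "#")
  need <- c("trial", "neuron", "Z", "H", "S", "X", "R")
  if (!all(need %in% names(out)))
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(out[need]))
    stop("trial table contains missing values", call. = FALSE)
  attr(out, "theta") <- theta
  class(out) <- c("spike_trials", "data.frame")
  out
}
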