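#' Online update of the causal reward-model parameters
#'
#' One stochastic-gradient step of the least-squares problem behind the
#' spiking-discontinuity fit, applied only when the trial's drive maximum
#' fell within the learning window (`theta - p <= Z < theta + p`); trials
#' outside the window leave the parameters unchanged.
#'
#' For the piecewise-constant model (`length(u) == 2`) the update decouples
#' by threshold side:
#' \deqn{\Delta\beta = -\eta(\gamma + \beta - R) \quad (Z \ge \theta), \qquad
#'   \Delta\gamma = -\eta(\gamma - R) \quad (Z < \theta),}
#' so the baseline tracks the sub-threshold reward and the effect estimate
#' tracks the super-threshold excess.  For the piecewise-linear model
#' (`length(u) == 4`) the full regression step is taken,
#' \deqn{u \leftarrow u - \eta (u^\top a - R)\, a, \qquad
#'   a = (1, H, H (Z - \theta), (1 - H)(Z - \theta)).}
#' In both cases the stationary points on a fixed in-window data set are
#' the batch least-squares solutions (for the constant model: the two side
#' means, i.e. the piecewise-constant discontinuity estimate); the second
#' component of `u` is the running causal-effect estimate.
#'
#' @param u Parameter vector: `(gamma, beta)` (length 2) or
#'   `(gamma, beta, alpha_r, alpha_l)` (length 4); the length selects the
#'   model order.
#' @param Z,H,R Trial summary values for the neuron.
#' @param theta Spike threshold.
#' @param p Window half-width; trials with `Z` outside
#'   `[theta - p, theta + p)` leave `u` unchanged.  `p = Inf` updates on
#'   every trial (observed-dependence limit).
#' @param eta Learning rate, `>= 0`.
#' @return The updated parameter vector.
#' @examples
#' online_causal_update(c(0, 0), Z = 1.01, H = 1, R = 2, theta = 1, p = 0.1,
#'                      eta = 0.05)
#' @export
online_causal_update <- function(u, Z, H, R, theta, p, eta) {
  stopifnot(length(u) %in% c(2L, 4L), eta >= 0, p > 0)
  if (Z < theta - p || Z >= theta + p) return(u)
  if (length(u) == 2L) {
    if (Z >= theta) u[2] <- u[2] - eta * (u[1] + u[2] - R)
    else u[1] <- u[1] - eta * (u[1] - R)
    return(u)
  }
  a <- c(1, H, H * (Z - theta), (1 - H) * (Z - theta))
  u - eta * (sum(u * a) - R) * a
}

#' Reward-gradient weight update
#'
#' Moves an input weight along the estimated reward gradient
#' \eqn{\partial E(R)/\partial w \approx (\partial E(H)/\partial w)\,\beta},
#' the product of the spike-probability sensitivity and the neuron's current
#' causal-effect estimate:
#' \deqn{w \leftarrow w + \mathrm{direction} \cdot \eta_w \,
#'   (\partial E(H)/\partial w)\, \beta.}
#' Applied every trial window, regardless of whether the window contributed
#' to the causal-model update.
#'
#' @param w Current weight.
#' @param beta Current causal-effect estimate.
#' @param dEH_dw Gradient of the per-window spike probability with respect to
#'   `w` (see [spike_prob_gradient()]).
#' @param eta_w Weight learning rate.
#' @param direction `+1` to ascend expected reward, `-1` to descend a cost.
#' @return The updated weight.
#' @export
weight_update <- function(w, beta, dEH_dw, eta_w, direction = -1) {
  stopifnot(eta_w >= 0, direction %in% c(-1, 1))
  w + direction * eta_w * dEH_dw * beta
}

#' Train a two-neuron LIF network with a causal-effect learning rule
#'
#' Alternates, window by window: simulate one trial window (state carries
#' over), update each neuron's causal-model parameters online
#' ([online_causal_update()]; only windows with drive within `p` of
#' threshold contribute), and update each input weight along the estimated
#' reward gradient ([weight_update()]; every window).  The
#' observed-dependence variant (`estimator = "od"`) is the same rule with an
#' unbounded window (`p = Inf`), so every trial updates the effect estimate
#' regardless of the drive.
#'
#' The spike-probability sensitivity \eqn{\partial E(H)/\partial w} is read
#' off a smooth interpolant of the analytic firing-rate quadrature, refreshed
#' once per run (weights move slowly relative to its curvature).
#'
#' @inheritParams simulate_run
#' @param estimator `"sde"` (windowed) or `"od"` (unbounded window).
#' @param order Reward-model order, 0 or 1 (see [online_causal_update()]).
#' @param p Window half-width for the SDE estimator.
#' @param eta_u Causal-model learning rate. Default 0.1.
#' @param eta_w Weight learning rate. Default 0.01.
#' @param n_seconds Simulated training duration (s); must be a multiple of
#'   the window length `params$T`.
#' @param w0 Initial weights (length 2).
#' @param direction `-1` (default) descends the quadratic cost; `+1`
#'   ascends.
#' @param w_range Weights are confined to this interval (the validity range
#'   of the firing-rate interpolant).
#' @param u0 Optional initial causal-model parameters (matrix, one row per
#'   neuron); default zeros.
#' @return An object of class `sde_train`: a data frame with one row per
#'   window (`time`, `w1`, `w2`, `beta1`, `beta2`, `gamma1`, `gamma2`,
#'   `reward`, plus `in_window` flags), with the configuration in
#'   attributes.  Supports `print()` and `plot()`.
#' @examples
#' set.seed(1)
#' fit <- sde_train(lif_params(), noise_spec(c = 0.01, n_neurons = 2),
#'                  network_weights(c(10, 10)), reward_spec("quadratic2"),
#'                  n_seconds = 2)
#' tail(fit, 3)
#' @export
sde_train <- function(params, noise, network, reward,
                      estimator = c("sde", "od"), order = 0, p = 0.3,
                      eta_u = 0.1, eta_w = 0.01, n_seconds = 20,
                      w0 = network$w1, direction = -1,
                      w_range = c(0.5, 25), u0 = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(params, "lif_params"), network$n2 == 0, network$n1 == 2)
  n_windows <- round(n_seconds / params$T)
  if (abs(n_windows * params$T - n_seconds) > 1e-8)
    stop("'n_seconds' must be a multiple of the window length T", call. = FALSE)
  p_eff <- if (estimator == "od") Inf else p
  npar <- if (order == 0) 2L else 4L
  u <- if (is.null(u0)) matrix(0, 2, npar) else u0
  stopifnot(nrow(u) == 2L, ncol(u) == npar)

  EH <- spike_prob_interpolant(params, noise$x_dc, noise$sigma,
                               w_range = w_range, dt = params$dt)
  w <- pmin(pmax(w0, w_range[1]), w_range[2])
  v_state <- rep(0, 2); s_state <- rep(0, 2)
  theta <- params$theta

  out <- matrix(NA_real_, n_windows, 11)
  colnames(out) <- c("time", "w1", "w2", "beta1", "beta2", "gamma1", "gamma2",
                     "reward", "in_window1", "in_window2", "mean_reward")
  run_mean <- 0
  for (k in seq_len(n_windows)) {
    kk <- lif_kernel(1L, params$steps_per_window, params$dt,
                     params$g_L, params$theta, params$v_r, params$ref_steps,
                     params$tau_s, params$syn_jump,
                     w, noise$x_dc, noise$sigma, noise$c,
                     NULL, NULL, noise$sigma2, v_state, s_state, FALSE)
    v_state <- kk$v_final; s_state <- kk$s_final
    R <- eval_reward(reward, kk$S, 2L)
    inw <- logical(2)
    for (i in 1:2) {
      Zi <- kk$Z[1, i]; Hi <- kk$H[1, i]
      inw[i] <- Zi >= theta - p_eff && Zi < theta + p_eff
      u[i, ] <- online_causal_update(u[i, ], Zi, Hi, R, theta, p_eff, eta_u)
      grad <- EH(w[i], deriv = 1)
      w[i] <- weight_update(w[i], u[i, 2], grad, eta_w, direction)
      w[i] <- min(max(w[i], w_range[1]), w_range[2])
    }
    run_mean <- run_mean + (R - run_mean) / k
    out[k, ] <- c(k * params$T, w[1], w[2], u[1, 2], u[2, 2], u[1, 1], u[2, 1],
                  R, inw[1], inw[2], run_mean)
  }
  out <- as.data.frame(out)
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  attr(out, "reward") <- reward
  attr(out, "estimator") <- estimator
  attr(out, "order") <- order
  attr(out, "p") <- p_eff
  attr(out, "eta_u") <- eta_u
  attr(out, "eta_w") <- eta_w
  attr(out, "w0") <- w0
  class(out) <- c("sde_train", "data.frame")
  out
}

#' @export
print.sde_train <- function(x, ...) {
  est <- attr(x, "estimator"); if (is.null(est)) est <- "?"
  ord <- attr(x, "order"); if (is.null(ord)) ord <- NA_integer_
  pp <- attr(x, "p"); if (is.null(pp)) pp <- NA_real_
  cat(sprintf("Training trajectory (%s estimator, order %s, p = %s): %d windows (%.1f s)\n",
              est, ord, format(pp), nrow(x), max(x$time)))
  cat(sprintf("  final w = (%.3g, %.3g), beta = (%.3g, %.3g), mean reward %.4g\n",
              x$w1[nrow(x)], x$w2[nrow(x)], x$beta1[nrow(x)], x$beta2[nrow(x)],
              x$mean_reward[nrow(x)]))
  invisible(x)
}

#' Plot a training trajectory
#'
#' Three panels: weight trajectory in the `(w1, w2)` plane, running
#' causal-effect estimates, and the running mean reward.
#'
#' @param x An `sde_train` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.sde_train <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$w1, x$w2, type = "l", xlab = "w1", ylab = "w2",
                 main = "weights")
  graphics::points(x$w1[1], x$w2[1], pch = 16, col = "steelblue")
  graphics::points(x$w1[nrow(x)], x$w2[nrow(x)], pch = 16, col = "firebrick")
  graphics::matplot(x$time, cbind(x$beta1, x$beta2), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "beta estimate", main = "effects")
  graphics::plot(x$time, x$mean_reward, type = "l", xlab = "time (s)",
                 ylab = "running mean reward", main = "reward")
  invisible(x)
}

#' Locate the reward optimum over a weight grid
#'
#' Grid search of the expected end-of-window reward over `(w1, w2)`,
#' estimating each cell by simulation.  Used as the reference optimum for
#' distance-to-optimum learning curves.
#'
#' @inheritParams simulate_run
#' @param w_grid Numeric vector of weights forming the grid in both axes.
#' @param n_windows Windows simulated per grid cell.
#' @param direction `-1`: the optimum minimizes expected reward (cost);
#'   `+1`: maximizes.
#' @return A list with `w_opt` (length-2 vector), `landscape` (data frame
#'   `w1, w2, mean_R`).
#' @export
find_optimal_weights <- function(params, noise, reward,
                                 w_grid = seq(1, 20, length.out = 12),
                                 n_windows = 200, direction = -1) {
  cells <- expand.grid(w1 = w_grid, w2 = w_grid)
  mean_R <- vapply(seq_len(nrow(cells)), function(j) {
    tr <- simulate_run(params, noise,
                       network_weights(c(cells$w1[j], cells$w2[j])),
                       reward, n_windows)
    mean(tr$R[tr$neuron == 1])
  }, numeric(1))
  best <- if (direction < 0) which.min(mean_R) else which.max(mean_R)
  list(w_opt = c(cells$w1[best], cells$w2[best]),
       landscape = cbind(cells, mean_R = mean_R))
}

#' Default configuration of the two-neuron learning experiments
#'
#' The operating point used by the reward-optimization experiments: the
#' quadratic two-neuron cost with a synaptic jump of 0.2 and a DC input of 4,
#' under which the expected cost has an interior valley (around input
#' weights `(5, 15)`) that is strictly better than the silent (never-spiking)
#' state, and the two neurons' true causal effects have opposite signs on
#' the approach to the valley.  Both features are needed for a meaningful
#' reward-learning benchmark: the first makes the optimum a genuine target,
#' the second is what lets confounding corrupt the naive gradient direction.
#'
#' @param c Noise correlation for the training runs.
#' @return A list with components `params`, `noise`, `network` (initial
#'   weights `(10, 6)`), `reward`, `p`, `eta_u`, `eta_w`, `w_range`.
#' @export
learning_defaults <- function(c = 0.01) {
  list(params = lif_params(syn_jump = 0.2),
       noise = noise_spec(x_dc = 4, c = c, n_neurons = 2),
       network = network_weights(c(10, 6)),
       reward = reward_spec("quadratic2"),
       p = 0.3, eta_u = 0.1, eta_w = 0.01, w_range = c(0.5, 25))
}

#' Compare causal-effect learning rules over repeated seeded runs
#'
#' Trains the two-neuron network `n_seeds` times with [sde_train()] for each
#' requested estimator and noise correlation, and reports the distance of
#' the final weights to the reward-optimal weights (located by grid search
#' on the expected-cost landscape at the uncorrelated operating point).
#'
#' @param estimators Estimators to compare (subset of `c("sde", "od")`).
#' @param c_values Noise correlations to train under.
#' @param n_seconds Training duration per run (s).
#' @param n_seeds Seeded runs per condition.
#' @param seed Base seed; run r uses `seed * 1000 + r`.
#' @param config Configuration list as from [learning_defaults()].
#' @param opt_grid,opt_windows Grid and per-cell windows for locating the
#'   optimum.
#' @return Data frame with one row per run: `estimator`, `c`, `seed`,
#'   `dist_initial`, `dist_final`, `w1`, `w2`.  The located optimum is in
#'   the `w_opt` attribute.
#' @export
run_learning_experiment <- function(estimators = c("sde", "od"),
                                    c_values = c(0.01, 0.5),
                                    n_seconds = 120, n_seeds = 50, seed = 1,
                                    config = learning_defaults(),
                                    opt_grid = seq(1, 21, by = 2),
                                    opt_windows = 400) {
  set.seed(seed)
  noise0 <- config$noise; noise0$c <- 0.01
  opt <- find_optimal_weights(config$params, noise0, config$reward,
                              w_grid = opt_grid, n_windows = opt_windows)
  w_opt <- opt$w_opt
  w0 <- config$network$w1
  d0 <- sqrt(sum((w0 - w_opt)^2))
  rows <- list()
  for (cc in c_values) for (est in estimators) for (r in seq_len(n_seeds)) {
    set.seed(seed * 1000 + r)
    noise_c <- config$noise; noise_c$c <- cc
    tr <- sde_train(config$params, noise_c, config$network, config$reward,
                    estimator = est, p = config$p, eta_u = config$eta_u,
                    eta_w = config$eta_w, n_seconds = n_seconds,
                    w_range = config$w_range)
    n <- nrow(tr)
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = est, c = cc, seed = seed * 1000 + r,
      dist_initial = d0,
      dist_final = sqrt((tr$w1[n] - w_opt[1])^2 + (tr$w2[n] - w_opt[2])^2),
      w1 = tr$w1[n], w2 = tr$w2[n])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "w_opt") <- w_opt
  attr(out, "landscape") <- opt$landscape
  out
}

#' Convergence time of the online causal-effect estimate
#'
#' Runs the online piecewise-constant rule (weights fixed) for `n_seeds`
#' seeded simulations, averages the running causal-effect estimate across
#' seeds, and reports the earliest simulated time after which the mean
#' trajectory stays within one standard error of its end-of-run value (the
#' standard error of the across-seed mean at the final window).
#'
#' @param n_seeds Number of seeded runs.
#' @param n_seconds Duration of each run (s).
#' @param seed Base seed; run r uses `seed * 1000 + r`.
#' @param config Configuration list as from [learning_defaults()];
#'   weights stay at `config$network$w1` throughout (`eta_w = 0`).
#' @param neuron Neuron whose estimate is tracked.
#' @param block_s Resolution (s) at which the averaged trajectory and its
#'   standard-error band are evaluated.
#' @return A list of class `sde_convergence`: `t_converge` (s), `se_band`,
#'   `beta_final` (asymptotic value: across-seed mean over the final 10\%),
#'   `block_mean`, `block_se`, `time` (block grid) and `mean_beta` (the
#'   per-window averaged trajectory).
#' @export
run_convergence_experiment <- function(n_seeds = 50, n_seconds = 30, seed = 1,
                                       config = learning_defaults(),
                                       neuron = 1, block_s = 1) {
  n_windows <- round(n_seconds / config$params$T)
  B <- matrix(NA_real_, n_seeds, n_windows)
  for (r in seq_len(n_seeds)) {
    set.seed(seed * 1000 + r)
    tr <- sde_train(config$params, config$noise, config$network,
                    config$reward, estimator = "sde", p = config$p,
                    eta_u = config$eta_u, eta_w = 0, n_seconds = n_seconds,
                    w_range = config$w_range)
    B[r, ] <- if (neuron == 1) tr$beta1 else tr$beta2
  }
  mean_beta <- colMeans(B)
  # aggregate into blocks of block_s seconds (the resolution at which the
  # mean-and-error-bar trajectory is read): per seed and block, average the
  # running estimate; across seeds, form mean and standard error per block
  wpb <- max(1L, round(block_s / config$params$T))
  n_blocks <- floor(n_windows / wpb)
  # per-seed trailing average over two blocks: the reward distribution is
  # heavy-tailed, so the raw estimate takes occasional large jumps that a
  # per-window trajectory would propagate straight into the across-seed mean
  ksm <- 2L * wpb
  smooth1 <- function(row) {
    cs <- cumsum(row)
    lead <- cs[seq_len(n_windows)]
    lag <- c(rep(0, ksm), cs)[seq_len(n_windows)]
    (lead - lag) / pmin(seq_len(n_windows), ksm)
  }
  Bs <- t(apply(B, 1, smooth1))
  blk <- function(row) row[seq_len(n_blocks) * wpb]
  Bb <- t(apply(Bs, 1, blk))
  block_mean <- colMeans(Bb)
  block_se <- apply(Bb, 2, stats::sd) / sqrt(n_seeds)
  # asymptote: across-seed mean over the final 10% of the run
  tail_blocks <- max(1L, ceiling(0.9 * n_blocks)):n_blocks
  beta_final <- mean(block_mean[tail_blocks])
  # The across-seed mean relaxes exponentially toward the asymptote, with
  # stationary noise on top (the mean of n_seeds autocorrelated estimates
  # wanders by about one standard error).  Convergence time is therefore
  # read off the fitted relaxation m(t) = A (1 - exp(-t / tau)): the
  # earliest time after which the fitted mean is, and remains, within one
  # standard error of the asymptote, i.e. tau * log(|A| / band).
  tw <- seq_len(n_windows) * config$params$T
  band <- mean(block_se[tail_blocks])
  fit <- tryCatch(stats::nls(
    mb ~ A * (1 - exp(-tw / tau)),
    data = list(mb = mean_beta, tw = tw),
    start = list(A = beta_final, tau = 1)), error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    t_conv <- unname(cf["tau"] * log(max(abs(cf["A"]) / band, 1)))
  } else {
    # fallback: first block from which every later block mean sits within
    # two standard errors of the asymptote (95% envelope)
    ok <- abs(block_mean - beta_final) <= 2 * block_se
    stays <- rev(cumprod(rev(ok))) == 1
    bidx <- which(stays)[1]
    t_conv <- if (is.na(bidx)) Inf else bidx * wpb * config$params$T
  }
  tb <- seq_len(n_blocks) * wpb * config$params$T
  structure(list(t_converge = t_conv, se_band = band,
                 beta_final = beta_final, relaxation_fit = fit,
                 block_mean = block_mean, block_se = block_se, time = tb,
                 mean_beta = mean_beta, n_seeds = n_seeds),
            class = "sde_convergence")
}

#' @export
print.sde_convergence <- function(x, ...) {
  cat(sprintf(
    "Online estimate convergence: %.2f s (mean over %d seeds within +-%.3g of final %.4g)\n",
    x$t_converge, x$n_seeds, x$se_band, x$beta_final))
  invisible(x)
}
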