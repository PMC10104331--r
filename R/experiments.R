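#' Experiment configuration
#'
#' Bundles an experiment id, its scale factors and the base parameter
#' objects, for use with [run_experiment()] and the command-line driver.
#' Configurations can be read from / written to YAML or JSON with
#' [read_experiment_config()] / [write_experiment_config()].
#'
#' @param experiment One of `"two_neuron_sweep"`, `"weight_sweep"`,
#'   `"learning"`, `"wide"`, `"deep"`, `"deltas"`, `"refractory_sweep"`.
#' @param params A [lif_params()].
#' @param noise A [noise_spec()].
#' @param network A [network_weights()] (ignored by drivers that build their
#'   own network, e.g. the wide/deep sweeps).
#' @param reward A [reward_spec()].
#' @param n_windows Windows per simulation.
#' @param n_repeats Repeat simulations per condition (`>= 1`).
#' @param seed Integer RNG seed for the experiment.
#' @param ... Additional driver-specific options (e.g. `c_grid`, `p_grid`,
#'   `N_grid`, `w_grid`, `refractory_grid`), stored as-is.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("two_neuron_sweep", "weight_sweep",
                                             "learning", "wide", "deep",
                                             "deltas", "refractory_sweep"),
                              params = lif_params(),
                              noise = noise_spec(n_neurons = 2),
                              network = network_weights(c(10, 10)),
                              reward = reward_spec("quadratic2"),
                              n_windows = 2000, n_repeats = 10, seed = 1, ...) {
  experiment <- match.arg(experiment)
  stopifnot(n_repeats >= 1)
  structure(list(experiment = experiment, params = params, noise = noise,
                 network = network, reward = reward,
                 n_windows = as.integer(n_windows),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), opts = list(...)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment '%s': %d windows x %d repeats, seed %d\n",
              x$experiment, x$n_windows, x$n_repeats, x$seed))
  invisible(x)
}

#' Run a configured experiment
#'
#' Dispatches an [experiment_config()] to the matching driver
#' ([run_two_neuron_sweep()], [run_weight_sweep()], [sde_train()],
#' [run_wide_network()], [run_deep_network()], [validate_delta_s_grid()],
#' [run_refractory_sweep()]) and, if `out_dir` is given, writes the result
#' table (CSV), the resolved configuration and seed (JSON) to it.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return The driver's result table/object, invisibly when writing.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  o <- config$opts
  res <- switch(config$experiment,
    two_neuron_sweep = do.call(run_two_neuron_sweep, c(list(
      params = config$params, noise = config$noise, network = config$network,
      reward = config$reward, n_windows = config$n_windows,
      n_repeats = config$n_repeats, seed = config$seed), o)),
    weight_sweep = do.call(run_weight_sweep, c(list(
      params = config$params, noise = config$noise, reward = config$reward,
      n_windows = config$n_windows, seed = config$seed), o)),
    learning = do.call(sde_train, c(list(
      params = config$params, noise = config$noise, network = config$network,
      reward = config$reward), o)),
    wide = do.call(run_wide_network, c(list(
      params = config$params, n_windows = config$n_windows,
      n_repeats = config$n_repeats, seed = config$seed), o)),
    deep = do.call(run_deep_network, c(list(
      params = config$params, n_windows = config$n_windows,
      seed = config$seed), o)),
    deltas = do.call(validate_delta_s_grid, o),
    refractory_sweep = do.call(run_refractory_sweep, c(list(
      params = config$params, noise = config$noise, reward = config$reward,
      n_windows = config$n_windows, seed = config$seed), o)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(res),
                     file.path(out_dir, paste0(config$experiment, ".csv")),
                     row.names = FALSE)
    write_experiment_config(config,
                            file.path(out_dir, "config.json"))
    invisible(res)
  } else res
}

#' Read / write experiment configurations
#'
#' Serializes an [experiment_config()] (including its parameter objects and
#' seed) to JSON or YAML, chosen by file extension, and reads it back.
#'
#' @param config An [experiment_config()].
#' @param file Path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_experiment_config()`: `file`, invisibly;
#'   `read_experiment_config()`: an `experiment_config`.
#' @export
write_experiment_config <- function(config, file) {
  stopifnot(inherits(config, "experiment_config"))
  x <- list(experiment = config$experiment,
            params = unclass(config$params)[c("g_L", "theta", "v_r",
                                              "refractory", "dt", "T",
                                              "tau_s", "syn_jump")],
            noise = unclass(config$noise),
            network = list(w1 = config$network$w1, V = config$network$V,
                           w2 = config$network$w2),
            reward = Filter(Negate(is.null), unclass(config$reward)),
            n_windows = config$n_windows, n_repeats = config$n_repeats,
            seed = config$seed, opts = config$opts,
            package_version = as.character(utils::packageVersion("spikecause")))
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  } else if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(x, file)
  } else stop("config file must end in .json, .yaml or .yml", call. = FALSE)
  invisible(file)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(file) {
  x <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
       else if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
       else stop("config file must end in .json, .yaml or .yml", call. = FALSE)
  net <- if (!is.null(x$network$V))
    network_weights(unlist(x$network$w1), matrix(unlist(x$network$V),
                    ncol = length(unlist(x$network$w1))), unlist(x$network$w2))
  else network_weights(unlist(x$network$w1))
  rw <- x$reward
  reward <- if (rw$kind == "quadratic2")
    reward_spec("quadratic2", a = rw$a, b = rw$b, x_r = rw$x_r)
  else reward_spec(rw$kind, U = unlist(rw$U), Y_target = rw$Y_target)
  do.call(experiment_config, c(list(
    experiment = x$experiment,
    params = do.call(lif_params, x$params),
    noise = do.call(noise_spec, x$noise[c("x_dc", "sigma", "c", "n_neurons",
                                          "sigma2")]),
    network = net, reward = reward, n_windows = x$n_windows,
    n_repeats = x$n_repeats, seed = x$seed), x$opts))
}

#' Rescale drive maxima to the unit interval
#'
#' Linearly maps the observed `Z` range of each neuron's trials to
#' `[0, 1]` (threshold included in the map), so that a window half-width of
#' `p = 1` always covers the full observed drive range and the SDE fit at
#' `p = 1` reduces to the observed dependence.  The applied ranges are
#' recorded in the `z_normalization` attribute.
#'
#' @param trials A `spike_trials` data frame.
#' @return The rescaled trials; the rescaled threshold (per neuron it is the
#'   same transform applied to `theta`) is stored per neuron in the
#'   `z_normalization` attribute, and `attr(, "theta")` is set to `NA` since
#'   it is no longer common across neurons.
#' @export
normalize_drive <- function(trials) {
  theta <- attr(trials, "theta")
  if (is.null(theta) || is.na(theta))
    stop("trials carry no 'theta' attribute", call. = FALSE)
  pieces <- split(seq_len(nrow(trials)), trials$neuron)
  norm <- lapply(pieces, function(idx) {
    z <- trials$Z[idx]
    lo <- min(z); hi <- max(z)
    if (hi <= lo) stop("degenerate drive range; cannot normalize", call. = FALSE)
    trials$Z[idx] <<- (z - lo) / (hi - lo)
    c(lo = lo, hi = hi, theta = (theta - lo) / (hi - lo))
  })
  attr(trials, "z_normalization") <- do.call(rbind, norm)
  attr(trials, "theta") <- NA_real_
  trials
}

#' Two-neuron bias/variance sweep over confounding and window size
#'
#' For each noise correlation `c` and window half-width `p`, repeats the
#' two-neuron simulation, fits the piecewise-constant (`sde0`) and
#' piecewise-linear (`sde1`) discontinuity estimators and the
#' observed-dependence baseline, and reports mean, spread and bias against
#' the unconfounded ground truth ([ground_truth_effect()]).  Drive maxima
#' are normalized per run to `[0, 1]` ([normalize_drive()]), so `p` is on
#' the unit scale and `p = 1` spans the full range (the observed-dependence
#' limit of `sde0`).
#'
#' @inheritParams simulate_run
#' @param c_grid Noise correlations to sweep.
#' @param p_grid Window half-widths (unit drive scale).
#' @param n_repeats Simulations per condition.
#' @param gt_windows Windows for the ground-truth run.
#' @param seed Integer seed.
#' @return Data frame with columns `c`, `p`, `method`, `neuron`,
#'   `mean_beta`, `sd_beta`, `beta_true`, `bias`, `n_fail`.
#' @export
run_two_neuron_sweep <- function(params = lif_params(),
                                 noise = noise_spec(n_neurons = 2),
                                 network = network_weights(c(10, 10)),
                                 reward = reward_spec("quadratic2"),
                                 c_grid = c(0.01, 0.25, 0.5, 0.75, 0.99),
                                 p_grid = c(0.03, 0.05, 0.1, 0.15, 0.3, 0.6, 1),
                                 n_windows = 2000, n_repeats = 10,
                                 gt_windows = 20000, seed = 1) {
  set.seed(seed)
  gt <- ground_truth_effect(params, noise, network, reward, gt_windows)
  rows <- list()
  for (cc in c_grid) {
    noise_c <- noise; noise_c$c <- cc
    est <- array(NA_real_,
                 c(n_repeats, 2L, length(p_grid) * 2L + 1L))  # sde0/sde1 x p + od
    for (r in seq_len(n_repeats)) {
      tr <- simulate_run(params, noise_c, network, reward, n_windows)
      trn <- normalize_drive(tr)
      zn <- attr(trn, "z_normalization")
      for (i in 1:2) {
        k <- 0L
        for (pp in p_grid) for (m in c(0, 1)) {
          k <- k + 1L
          est[r, i, k] <- tryCatch(
            sde_fit(trn, i, p = pp, theta = zn[i, "theta"], order = m)$beta,
            error = function(e) NA_real_)
        }
        est[r, i, k + 1L] <- tryCatch(as.numeric(observed_dependence(tr, i)),
                                      error = function(e) NA_real_)
      }
    }
    k <- 0L
    for (pp in p_grid) for (m in c(0, 1)) {
      k <- k + 1L
      for (i in 1:2) {
        v <- est[, i, k]
        rows[[length(rows) + 1L]] <- data.frame(
          c = cc, p = pp, method = paste0("sde", m), neuron = i,
          mean_beta = mean(v, na.rm = TRUE), sd_beta = stats::sd(v, na.rm = TRUE),
          beta_true = gt$beta_true[i],
          bias = mean(v, na.rm = TRUE) - gt$beta_true[i],
          n_fail = sum(is.na(v)))
      }
    }
    for (i in 1:2) {
      v <- est[, i, k + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        c = cc, p = NA_real_, method = "od", neuron = i,
        mean_beta = mean(v, na.rm = TRUE), sd_beta = stats::sd(v, na.rm = TRUE),
        beta_true = gt$beta_true[i],
        bias = mean(v, na.rm = TRUE) - gt$beta_true[i],
        n_fail = sum(is.na(v)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- gt
  attr(out, "seed") <- seed
  out
}

#' Estimator quality across the two-neuron weight plane
#'
#' Sweeps the input weights `(w1, w2)` over a grid, and per cell records the
#' firing statistics (rate, inter-spike-interval coefficient of variation)
#' and the relative error of the piecewise-constant discontinuity and
#' observed-dependence estimates against the unconfounded ground truth.
#' Also reports, per cell, the angle between each estimated reward-gradient
#' vector \eqn{(\partial E(H_i)/\partial w_i \cdot \hat\beta_i)_i} and the
#' true gradient obtained by finite differences of the mean-reward surface
#' across the grid.  Cells in which a neuron never (or always) spikes are
#' flagged with `NA` estimates.
#'
#' @inheritParams simulate_run
#' @param w_grid Weights forming the grid on each axis (within `[1, 20]`).
#' @param p Window half-width (unit drive scale).
#' @param n_repeats Simulations averaged per cell (the per-cell estimates are
#'   means over repeats, so with several repeats the error columns reflect
#'   bias rather than single-run noise).
#' @param gt_windows Windows for each cell's ground-truth run.
#' @param seed Integer seed.
#' @return Data frame with one row per grid cell and neuron: `w1`, `w2`,
#'   `neuron`, `rate`, `isi_cv`, `beta_true`, `beta_sde`, `beta_od`,
#'   `rel_error_sde`, `rel_error_od`, `grad_angle_sde`, `grad_angle_od`,
#'   `mean_R`.
#' @export
run_weight_sweep <- function(params = lif_params(),
                             noise = noise_spec(c = 0.5, n_neurons = 2),
                             reward = reward_spec("quadratic2"),
                             w_grid = seq(1, 20, length.out = 8),
                             p = 0.1, n_windows = 2000, n_repeats = 1,
                             gt_windows = 8000, seed = 1, eps = 1e-6) {
  set.seed(seed)
  nw <- length(w_grid)
  cells <- expand.grid(w1 = w_grid, w2 = w_grid)
  per <- vector("list", nrow(cells))
  meanR <- matrix(NA_real_, nw, nw)
  for (j in seq_len(nrow(cells))) {
    net <- network_weights(c(cells$w1[j], cells$w2[j]))
    gt <- tryCatch(ground_truth_effect(params, noise, net, reward, gt_windows),
                   error = function(e)
                     data.frame(neuron = 1:2, beta_true = NA_real_,
                                se = NA_real_))
    b_sde <- b_od <- matrix(NA_real_, n_repeats, 2L)
    rate <- isi_cv <- rep(NA_real_, 2L)
    for (r in seq_len(n_repeats)) {
      tr <- simulate_run(params, noise, net, reward, n_windows,
                         record_spikes = (r == 1L))
      if (r == 1L) {
        meanR[match(cells$w1[j], w_grid), match(cells$w2[j], w_grid)] <-
          mean(tr$R[tr$neuron == 1])
        st <- attr(tr, "spike_times")
        for (i in 1:2) {
          isi <- diff(st[[i]])
          isi_cv[i] <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_
          rate[i] <- length(st[[i]]) / (n_windows * params$T)
        }
      }
      trn <- normalize_drive_safe(tr)
      zn <- if (!is.null(trn)) attr(trn, "z_normalization")
      for (i in 1:2) {
        if (!is.null(trn))
          b_sde[r, i] <- tryCatch(
            sde_fit(trn, i, p = p, theta = zn[i, "theta"], order = 0)$beta,
            error = function(e) NA_real_)
        b_od[r, i] <- tryCatch(as.numeric(observed_dependence(tr, i)),
                               error = function(e) NA_real_)
      }
    }
    res <- lapply(1:2, function(i) {
      beta_sde <- mean(b_sde[, i], na.rm = TRUE)
      beta_od <- mean(b_od[, i], na.rm = TRUE)
      data.frame(w1 = cells$w1[j], w2 = cells$w2[j], neuron = i,
                 rate = rate[i], isi_cv = isi_cv[i],
                 beta_true = gt$beta_true[i],
                 beta_sde = beta_sde, beta_od = beta_od,
                 rel_error_sde = abs(beta_sde - gt$beta_true[i]) /
                   pmax(abs(gt$beta_true[i]), eps),
                 rel_error_od = abs(beta_od - gt$beta_true[i]) /
                   pmax(abs(gt$beta_true[i]), eps))
    })
    per[[j]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL

  # gradient fields over the grid: true from the mean-reward surface,
  # estimated from dE(H)/dw * beta_hat
  gR1 <- grid_gradient(meanR, w_grid, along = 1)
  gR2 <- grid_gradient(meanR, w_grid, along = 2)
  EH <- spike_prob_interpolant(params, noise$x_dc, noise$sigma,
                               w_range = range(w_grid) + c(-0.5, 0.5),
                               dt = params$dt)
  out$grad_angle_sde <- NA_real_
  out$grad_angle_od <- NA_real_
  out$mean_R <- NA_real_
  for (j in seq_len(nrow(cells))) {
    i1 <- match(cells$w1[j], w_grid); i2 <- match(cells$w2[j], w_grid)
    true_g <- c(gR1[i1, i2], gR2[i1, i2])
    rows_j <- which(out$w1 == cells$w1[j] & out$w2 == cells$w2[j])
    dEH <- EH(c(cells$w1[j], cells$w2[j]), deriv = 1)
    est_sde <- dEH * out$beta_sde[rows_j]
    est_od <- dEH * out$beta_od[rows_j]
    out$grad_angle_sde[rows_j] <- angle_deg(est_sde, true_g)
    out$grad_angle_od[rows_j] <- angle_deg(est_od, true_g)
    out$mean_R[rows_j] <- meanR[i1, i2]
  }
  attr(out, "mean_R_surface") <- meanR
  attr(out, "w_grid") <- w_grid
  attr(out, "seed") <- seed
  out
}

normalize_drive_safe <- function(trials) {
  tryCatch(normalize_drive(trials), error = function(e) NULL)
}

grid_gradient <- function(M, g, along = 1) {
  n <- length(g)
  G <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (along == 1) {
      lo <- max(i - 1, 1); hi <- min(i + 1, n)
      G[i, j] <- (M[hi, j] - M[lo, j]) / (g[hi] - g[lo])
    } else {
      lo <- max(j - 1, 1); hi <- min(j + 1, n)
      G[i, j] <- (M[i, hi] - M[i, lo]) / (g[hi] - g[lo])
    }
  }
  G
}

angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (!is.finite(na) || !is.finite(nb) || na == 0 || nb == 0) return(NA_real_)
  acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
}

#' Wide single-hidden-layer network sweep
#'
#' Simulates a single hidden layer of `N` LIF neurons with shared-plus-
#' private noise and reward \eqn{R = |U \cdot s - Y|}, for each layer width
#' and noise correlation.  Per condition it estimates every neuron's causal
#' effect with the piecewise-constant discontinuity estimator and the
#' observed dependence, and scores both against the unconfounded (`c = 0`)
#' ground truth with [effect_metrics()].  The readout `U` is drawn once per
#' width from N(0, `U_var`) and shared across correlations and repeats, so
#' the same network is compared across confounding levels.
#'
#' @param params A [lif_params()].
#' @param N_grid Hidden-layer widths.
#' @param c_grid Noise correlations.
#' @param x_dc DC input (weights are all ones, so this sets the operating
#'   point).
#' @param sigma Noise magnitude.
#' @param U_var Variance of the readout weights. Default 5.
#' @param Y_target Readout target. Default 0.1.
#' @param p Window half-width (unit drive scale).
#' @param n_windows Windows per run.
#' @param n_repeats Repeats per condition.
#' @param gt_windows Windows for each width's ground-truth run.
#' @param seed Integer seed.
#' @return Data frame with columns `N`, `c`, `method`, `mse`,
#'   `alignment_deg` (means over repeats), plus `mse_sd`.
#' @export
run_wide_network <- function(params = lif_params(), N_grid = c(2, 10, 30),
                             c_grid = c(0.01, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99),
                             x_dc = 48, sigma = 10 * sqrt(0.001), U_var = 5,
                             Y_target = 0.1, p = 0.05, n_windows = 2000,
                             n_repeats = 10, gt_windows = 20000, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (N in N_grid) {
    U <- stats::rnorm(N, 0, sqrt(U_var))
    reward <- reward_spec("linear_readout", U = U, Y_target = Y_target)
    net <- network_weights(rep(1, N))
    noise0 <- noise_spec(x_dc = x_dc, sigma = sigma, c = 0, n_neurons = N)
    gt <- ground_truth_effect(params, noise0, net, reward, gt_windows)
    for (cc in c_grid) {
      noise_c <- noise0; noise_c$c <- cc
      m_sde <- m_od <- a_sde <- a_od <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        tr <- simulate_run(params, noise_c, net, reward, n_windows)
        trn <- normalize_drive_safe(tr)
        zn <- if (!is.null(trn)) attr(trn, "z_normalization")
        b_sde <- vapply(seq_len(N), function(i) {
          if (is.null(trn)) return(NA_real_)
          tryCatch(sde_fit(trn, i, p = p, theta = zn[i, "theta"], order = 0)$beta,
                   error = function(e) NA_real_)
        }, numeric(1))
        b_od <- vapply(seq_len(N), function(i)
          tryCatch(as.numeric(observed_dependence(tr, i)),
                   error = function(e) NA_real_), numeric(1))
        ok <- stats::complete.cases(b_sde, b_od, gt$beta_true)
        ms <- effect_metrics(b_sde[ok], gt$beta_true[ok])
        mo <- effect_metrics(b_od[ok], gt$beta_true[ok])
        m_sde[r] <- ms$mse; a_sde[r] <- ms$alignment_deg
        m_od[r] <- mo$mse; a_od[r] <- mo$alignment_deg
      }
      rows[[length(rows) + 1L]] <- data.frame(
        N = N, c = cc, method = c("sde0", "od"),
        mse = c(mean(m_sde), mean(m_od)),
        mse_sd = c(stats::sd(m_sde), stats::sd(m_od)),
        alignment_deg = c(mean(a_sde), mean(a_od)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Two-hidden-layer (deep) network estimation
#'
#' Simulates a two-layer LIF network (widths `N`), with correlated noise
#' into the first layer and private noise only in the second, and reward
#' \eqn{R = |U \cdot s^{(2)} - Y|} read from the second layer.  First-layer
#' causal effects are estimated with the piecewise-constant discontinuity
#' estimator over a grid of window sizes and with the observed dependence,
#' under both the correlated and an uncorrelated input condition; ground
#' truth is the observed dependence at `c = 0` on a long run.
#'
#' The inter-layer weights `V` are drawn from N(`V_mean`, `V_sd^2`).  The
#' second-layer input weight is auto-calibrated from a pilot run so the mean
#' second-layer drive sits mid-way to threshold (`0.5 * theta * g_L`),
#' keeping the output layer in the fluctuation-driven regime.
#'
#' @param params A [lif_params()].
#' @param N Neurons per hidden layer. Default 10.
#' @param c Correlation of the first-layer noise in the confounded
#'   condition. Default 0.5.
#' @param x_dc First-layer DC input. Default 48 (weights of ones).
#' @param sigma First-layer noise magnitude.
#' @param V_mean,V_sd Distribution of inter-layer weights. Defaults 100, 200.
#' @param Y_target Readout target. Default 0.02.
#' @param p_grid Window half-widths (unit drive scale).
#' @param n_windows Windows per condition run.
#' @param gt_windows Windows for the ground-truth run.
#' @param seed Integer seed.
#' @return Data frame with columns `neuron`, `p`, `method`, `condition`
#'   (`"correlated"`/`"uncorrelated"`), `beta_hat`, `beta_true`.
#' @export
run_deep_network <- function(params = lif_params(), N = 10, c = 0.5,
                             x_dc = 48, sigma = 10 * sqrt(0.001),
                             V_mean = 100, V_sd = 200, Y_target = 0.02,
                             p_grid = c(0.05, 0.1, 0.2, 0.4), n_windows = 4000,
                             gt_windows = 20000, seed = 1) {
  set.seed(seed)
  V <- matrix(stats::rnorm(N * N, V_mean, V_sd), N, N)
  reward <- reward_spec("deep_readout", U = rep(1, N), Y_target = Y_target)

  # pilot: first layer alone, to size the second-layer input weight
  pilot_net <- network_weights(rep(1, N))
  pilot_noise <- noise_spec(x_dc = x_dc, sigma = sigma, c = 0, n_neurons = N)
  pilot <- simulate_run(params, pilot_noise,
                        pilot_net, reward_spec("linear_readout",
                                               U = rep(1, N), Y_target = 0),
                        max(200L, min(1000L, n_windows)))
  s_bar <- vapply(seq_len(N), function(i) mean(pilot$S[pilot$neuron == i]),
                  numeric(1))
  drive_scale <- mean(pmax(V %*% s_bar, 0))
  w2 <- rep(0.5 * params$theta * params$g_L / max(drive_scale, 1e-8), N)
  net <- network_weights(rep(1, N), V = V, w2 = w2)

  noise0 <- noise_spec(x_dc = x_dc, sigma = sigma, c = 0, n_neurons = N)
  gt <- ground_truth_effect(params, noise0, net, reward, gt_windows)

  rows <- list()
  for (cond in c("uncorrelated", "correlated")) {
    noise_c <- noise0
    noise_c$c <- if (cond == "correlated") c else 0.01
    tr <- simulate_run(params, noise_c, net, reward, n_windows)
    trn <- normalize_drive_safe(tr)
    zn <- if (!is.null(trn)) attr(trn, "z_normalization")
    for (i in seq_len(N)) {
      for (pp in p_grid) {
        bh <- if (is.null(trn)) NA_real_ else tryCatch(
          sde_fit(trn, i, p = pp, theta = zn[i, "theta"], order = 0)$beta,
          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          neuron = i, p = pp, method = "sde0", condition = cond,
          beta_hat = bh, beta_true = gt$beta_true[i])
      }
      bod <- tryCatch(as.numeric(observed_dependence(tr, i)),
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        neuron = i, p = NA_real_, method = "od", condition = cond,
        beta_hat = bod, beta_true = gt$beta_true[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "w2") <- w2
  attr(out, "seed") <- seed
  out
}

#' Estimation error across refractory periods
#'
#' Repeats a reduced weight-sweep error analysis for several absolute
#' refractory periods and summarizes the distribution of the
#' piecewise-constant discontinuity estimator's relative error per value.
#'
#' @inheritParams run_weight_sweep
#' @param refractory_grid Refractory periods (s). Default 1, 3, 5 ms.
#' @return Data frame with one row per refractory value: `refractory_ms`,
#'   `n_cells`, `median_rel_error`, `q25`, `q75`, `mean_rel_error`.  The per-
#'   cell table is attached as the `cells` attribute.
#' @export
run_refractory_sweep <- function(params = lif_params(),
                                 noise = noise_spec(n_neurons = 2),
                                 reward = reward_spec("quadratic2"),
                                 refractory_grid = c(0.001, 0.003, 0.005),
                                 w_grid = seq(4, 20, length.out = 4),
                                 p = 0.1, n_windows = 1500,
                                 gt_windows = 6000, seed = 1) {
  all_cells <- list()
  rows <- lapply(refractory_grid, function(rf) {
    pr <- lif_params(g_L = params$g_L, theta = params$theta, v_r = params$v_r,
                     refractory = rf, dt = params$dt, T = params$T,
                     tau_s = params$tau_s, syn_jump = params$syn_jump)
    sw <- run_weight_sweep(pr, noise, reward, w_grid = w_grid, p = p,
                           n_windows = n_windows, gt_windows = gt_windows,
                           seed = seed)
    sw$refractory_ms <- rf * 1000
    all_cells[[length(all_cells) + 1L]] <<- sw
    e <- sw$rel_error_sde[is.finite(sw$rel_error_sde)]
    data.frame(refractory_ms = rf * 1000, n_cells = length(e),
               median_rel_error = stats::median(e),
               q25 = stats::quantile(e, 0.25, names = FALSE),
               q75 = stats::quantile(e, 0.75, names = FALSE),
               mean_rel_error = mean(e))
  })
  out <- do.call(rbind, rows)
  attr(out, "cells") <- do.call(rbind, all_cells)
  attr(out, "seed") <- seed
  out
}
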