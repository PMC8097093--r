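#' Simulation configuration
#'
#' Collects every loop parameter of the user-learning / co-adaptation
#' simulations. Defaults follow the simulated experimental sessions: 8 sensor
#' channels mapped to a 2-D device, 40,000 iterations (roughly 10-15 min of
#' interaction at 50 Hz), smoothing \eqn{\alpha = 0.99, \beta = 0.15},
#' regularization noise variance \eqn{10^{-4}} and 20 repetitions per
#' condition.
#'
#' @param n input dimension (default 8).
#' @param m output dimension (default 2).
#' @param K iterations per run (default 40000).
#' @param eta user base learning rate in \eqn{(0, 1]}.
#' @param gamma interface adaptation rate in \eqn{[0, 1]}; 0 means a static
#'   map.
#' @param alpha,beta ARMA smoothing parameters of the dependent action
#'   sequence.
#' @param noise_var variance of the regularization noise (default 1e-4).
#' @param mode one of \code{"independent"}, \code{"dependent"},
#'   \code{"coadapt"}, \code{"playback"}. \code{coadapt} requires
#'   \code{gamma > 0}.
#' @param n_runs repetitions per condition (default 20).
#' @param seed master seed; every child RNG stream is derived from it.
#' @param record_stride thinning of the stored metric series (default 10).
#' @param final_window unthinned final window over which summaries are
#'   averaged (default 200 iterations).
#' @return A validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n = 8, m = 2, K = 40000, eta = 1e-3, gamma = 0,
                              alpha = 0.99, beta = 0.15, noise_var = 1e-4,
                              mode = c("dependent", "independent", "coadapt",
                                       "playback"),
                              n_runs = 20, seed = 1, record_stride = 10,
                              final_window = 200) {
  mode <- match.arg(mode)
  if (K < 1) stop("K must be >= 1")
  if (m >= n) stop("m must be smaller than n")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (mode == "coadapt" && gamma == 0)
    stop("coadapt mode requires gamma > 0 (use mode = 'dependent' for a static map)")
  if (alpha < 0 || alpha >= 1) stop("alpha must satisfy 0 <= alpha < 1")
  if (beta <= 0) stop("beta must be positive")
  if (noise_var < 0) stop("noise_var must be non-negative")
  if (record_stride < 1) stop("record_stride must be >= 1")
  structure(
    list(n = as.integer(n), m = as.integer(m), K = as.integer(K),
         eta = eta, gamma = gamma, alpha = alpha, beta = beta,
         noise_var = noise_var, mode = mode, n_runs = as.integer(n_runs),
         seed = as.integer(seed), record_stride = as.integer(record_stride),
         final_window = as.integer(final_window)),
    class = "sim_config"
  )
}

mode_code <- function(mode) {
  match(mode, c("independent", "dependent", "coadapt", "playback")) - 1L
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-style derivation so that every (grid cell, run) pair
#' has its own reproducible RNG stream and adding cells or runs never perturbs
#' the seeds of existing ones.
#'
#' @param master master seed (integer).
#' @param cell grid-cell index (1-based; 0 for non-grid runs).
#' @param run run index (1-based).
#' @return Integer seed below \eqn{2^{31}}.
#' @export
derive_seed <- function(master, cell = 0, run = 1) {
  if (run < 0 || run > 100000) stop("run index out of range")
  as.integer(((master %% 100000) * 20011 + cell * 100003 + run) %% 2147483647)
}

run_core <- function(config, map, state, playback = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(map, "interface_map"),
            inherits(state, "generative_state"))
  if (map$n_in != config$n || length(state$mean) != config$n)
    stop("map/state dimension does not match the configuration (n = ",
         config$n, ")")
  if (map$n_out != config$m) stop("map output dimension must equal m")
  if (state$task_dim != config$m) stop("state task_dim must equal m")
  if (is.null(playback)) playback <- matrix(0, 0, 0)

  res <- sim_core_cpp(
    W = state$components, lam_reg = state$lambda_reg, mu = state$mean,
    Btilde = t(map$scaled), lam0 = state$initial_spectrum,
    K = config$K, eta = config$eta, gamma = config$gamma,
    alpha = config$alpha, beta = config$beta,
    noise_sd = sqrt(config$noise_var), mode = mode_code(config$mode),
    playback = playback, record_stride = config$record_stride,
    final_window = min(config$final_window, config$K)
  )

  fw <- res$final_window
  colnames(fw) <- c("iteration", "planarity", "angle_deg", "vaf_pct", "reward")
  series <- data.frame(iteration = res$iteration, planarity = res$planarity,
                       angle_deg = res$angle_deg, vaf_pct = res$vaf_pct,
                       reward = res$reward)
  out <- list(
    config = config,
    series = series,
    final_window = as.data.frame(fw),
    conservation = data.frame(sum_m = res$cons_sum_m, frac_m = res$cons_frac),
    state = generative_state(res$W, task_dim = config$m, mean = drop(res$mu),
                             lambda_reg = drop(res$lambda_reg),
                             initial_spectrum = state$initial_spectrum),
    map = interface_map(t(res$Btilde))
  )
  out$final <- summarize_final_impl(out$final_window,
                                    min(config$final_window, config$K))
  class(out) <- "coadapt_run"
  out
}

#' @export
print.coadapt_run <- function(x, ...) {
  cat("<coadapt_run> mode =", x$config$mode, ", K =", x$config$K,
      ", eta =", x$config$eta, ", gamma =", x$config$gamma, "\n")
  cat(sprintf("final (last %d iters): planarity %.3f, angle %.2f deg, VAF %.1f%%, reward %.3f\n",
              nrow(x$final_window), x$final$planarity, x$final$angle_deg,
              x$final$vaf_pct, x$final$reward))
  invisible(x)
}

#' Simulate a user learning a static interface
#'
#' Runs the user-learning loop for \code{K} iterations against a fixed map:
#' draw \eqn{q_k \sim N(0, \Sigma_k)}, form the control signal (the raw draw
#' in \code{independent} mode, the ARMA-smoothed trajectory in
#' \code{dependent} mode), project, reward, reward-weighted incremental update
#' of the user eigenstructure, variance regularization, covariance rebuild.
#' Metrics (planarity, subspace angle, VAF, reward) are recorded every
#' \code{record_stride} iterations plus unthinned over the final window. The
#' run is a pure function of (config, seeds, init): seed the RNG before
#' calling (or use \code{\link{run_grid}}).
#'
#' @param config a \code{\link{simulation_config}} with mode
#'   \code{"independent"} or \code{"dependent"} (gamma is ignored; the map is
#'   static).
#' @param map initial \code{\link{interface_map}}.
#' @param init initial \code{\link{generative_state}}.
#' @return A \code{coadapt_run}: list with \code{series} (thinned metric
#'   trace), \code{final_window} (unthinned final window), \code{final}
#'   (final-window means), \code{conservation} (per-iteration first-m variance
#'   sum and fraction), and the final \code{state} and \code{map}.
#' @export
run_user_learning <- function(config, map, init) {
  if (!config$mode %in% c("independent", "dependent"))
    stop("run_user_learning requires mode 'independent' or 'dependent'")
  cfg <- config
  cfg$gamma <- 0          # static map
  run_core(cfg, map, init)
}

#' Simulate user-interface co-adaptation
#'
#' As \code{\link{run_user_learning}} with dependent sampling, plus an
#' unsupervised incremental-PCA update of the interface map (rate
#' \code{gamma}) at the end of every iteration, in the canonical loop order:
#' draw, smooth, project, reward, user update, regularize, rebuild, map
#' update. With \code{gamma = 0} the loop reduces bit-identically to
#' dependent-mode user learning under a shared seed.
#'
#' @param config a \code{\link{simulation_config}} with mode
#'   \code{"coadapt"} (or \code{"dependent"} with \code{gamma = 0} for the
#'   reduction case).
#' @inheritParams run_user_learning
#' @return A \code{coadapt_run}; see \code{\link{run_user_learning}}.
#' @export
run_coadaptation <- function(config, map, init) {
  if (!config$mode %in% c("coadapt", "dependent"))
    stop("run_coadaptation requires mode 'coadapt' (or 'dependent' with gamma = 0)")
  cfg <- config
  cfg$mode <- "coadapt"
  if (cfg$gamma == 0) cfg$mode <- "dependent"   # exact reduction, same stream
  run_core(cfg, map, init)
}

#' Drive the user model with a recorded (or synthetic) sequence
#'
#' Replaces the generative draw with successive rows of a multichannel
#' sequence (playback/emulation mode): the sequence rows are taken as the
#' smooth control signals, the model is non-centered (the mean estimate is
#' updated alongside the eigenstructure, and updates are computed on
#' mean-centered inputs). The only randomness left is the seeded
#' regularization noise, so a sequence needs to be simulated only once per
#' learning rate.
#'
#' @param sequence numeric matrix, at least \code{K} rows and exactly \code{n}
#'   columns.
#' @param config a \code{\link{simulation_config}} with mode
#'   \code{"playback"}.
#' @inheritParams run_user_learning
#' @return A \code{coadapt_run}; see \code{\link{run_user_learning}}.
#' @export
run_playback <- function(sequence, config, map, init) {
  if (config$mode != "playback") stop("run_playback requires mode 'playback'")
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != config$n)
    stop("sequence has ", ncol(sequence), " columns, expected n = ", config$n)
  if (nrow(sequence) < config$K)
    stop("sequence has ", nrow(sequence), " rows, fewer than K = ", config$K)
  run_core(config, map, init, playback = sequence)
}

#' Final-window summary of a run
#'
#' Mean of each metric over the last \code{window} (unthinned) iterations, the
#' standard endpoint summary of a simulation.
#'
#' @param result a \code{coadapt_run}.
#' @param window number of final iterations to average (default 200; must not
#'   exceed the stored final window).
#' @return Named list: \code{planarity}, \code{angle_deg}, \code{vaf_pct},
#'   \code{reward}.
#' @export
summarize_final <- function(result, window = 200) {
  stopifnot(inherits(result, "coadapt_run"))
  summarize_final_impl(result$final_window, window)
}

summarize_final_impl <- function(final_window, window) {
  if (window < 1) stop("window must be >= 1")
  if (window > nrow(final_window))
    stop("stored final window has only ", nrow(final_window),
         " iterations (requested ", window, ")")
  fw <- final_window[seq.int(nrow(final_window) - window + 1,
                             nrow(final_window)), , drop = FALSE]
  list(planarity = mean(fw$planarity), angle_deg = mean(fw$angle_deg),
       vaf_pct = mean(fw$vaf_pct), reward = mean(fw$reward))
}

#' Learning-rate grid experiment
#'
#' Runs every \eqn{(\eta, \gamma)} cell of a learning-rate grid for
#' \code{n_runs} seeded repetitions each, all starting from one shared
#' reference initial condition so cells are comparable. Child seeds are
#' derived deterministically from \code{(master seed, cell, run)}; re-running
#' with the same master seed reproduces the aggregate table bit-identically,
#' and adding cells never perturbs existing ones.
#'
#' @param base a \code{\link{simulation_config}}; its \code{eta}/\code{gamma}
#'   are overridden cell by cell, its \code{mode} must be \code{"coadapt"} or
#'   \code{"dependent"}/\code{"independent"} (\code{gamma_list} must then be
#'   0).
#' @param eta_list,gamma_list learning-rate values spanning the grid.
#' @param init_factory zero-argument function returning
#'   \code{list(state = , map = )}; called once per run so every run starts
#'   from an identical fresh copy. (Use \code{\link{make_reference_init}}
#'   under a fixed seed to build one.)
#' @param fit_tau if \code{TRUE} (default), fit the exponential convergence
#'   model to each run's angle trace and report \eqn{\tau} gated at
#'   \eqn{R^2 \ge 0.40}.
#' @param keep_runs if \code{TRUE}, also return every \code{coadapt_run}
#'   (memory-heavy for large grids).
#' @return List with \code{summary}: one tidy data frame with columns
#'   \code{run_id, eta, gamma, seed, final_planarity, final_angle_deg,
#'   final_vaf_pct, final_reward, tau_iterations, r_squared} (one row per
#'   run), and \code{runs} (list, or \code{NULL}).
#' @export
run_grid <- function(base, eta_list, gamma_list, init_factory,
                     fit_tau = TRUE, keep_runs = FALSE) {
  stopifnot(inherits(base, "sim_config"))
  if (!length(eta_list) || !length(gamma_list))
    stop("eta_list and gamma_list must be non-empty")
  cells <- expand.grid(eta = as.numeric(eta_list),
                       gamma = as.numeric(gamma_list))
  rows <- vector("list", nrow(cells) * base$n_runs)
  runs <- if (keep_runs) vector("list", length(rows)) else NULL
  rid <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (run in seq_len(base$n_runs)) {
      rid <- rid + 1L
      cfg <- base
      cfg$eta <- cells$eta[ci]
      cfg$gamma <- cells$gamma[ci]
      init <- init_factory()
      child <- derive_seed(base$seed, ci, run)
      set.seed(child)
      res <- if (cfg$mode == "coadapt") run_coadaptation(cfg, init$map, init$state)
             else run_user_learning(cfg, init$map, init$state)
      tau <- NA_real_; r2 <- NA_real_
      if (fit_tau) {
        fit <- fit_convergence(res$series$angle_deg, res$series$iteration)
        if (fit$converged) {
          r2 <- fit$r_squared
          if (r2 >= 0.40) tau <- fit$tau
        }
      }
      rows[[rid]] <- data.frame(
        run_id = rid, eta = cfg$eta, gamma = cfg$gamma, seed = child,
        final_planarity = res$final$planarity,
        final_angle_deg = res$final$angle_deg,
        final_vaf_pct = res$final$vaf_pct,
        final_reward = res$final$reward,
        tau_iterations = tau, r_squared = r2
      )
      if (keep_runs) runs[[rid]] <- res
    }
  }
  list(summary = do.call(rbind, rows), runs = runs)
}
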