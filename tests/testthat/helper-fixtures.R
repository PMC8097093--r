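# Shared fixtures and independent reference implementations used as oracles.

# random m x n matrix with orthonormal rows
rand_orthonormal_rows <- function(m, n) {
  Q <- qr.Q(qr(matrix(rnorm(n * m), n, m)))
  t(Q)
}

# the reference initial condition used across engine tests (cached)
.fixture_env <- new.env()
ref_fixture <- function() {
  if (is.null(.fixture_env$ref)) {
    set.seed(42)
    .fixture_env$ref <- make_reference_init()
  }
  .fixture_env$ref
}

# R-level reference loop composed of the exported single-step operations;
# independent of the compiled engine, consuming the same RNG stream layout.
r_reference_loop <- function(cfg, map, state, K) {
  sm <- NULL
  if (cfg$mode %in% c("dependent", "coadapt")) {
    q0 <- draw_action(state)
    sm <- smoothing_state(q0, cfg$alpha, cfg$beta)
  }
  for (k in seq_len(K)) {
    q <- draw_action(state)
    s <- if (is.null(sm)) q else { sm <- smooth_step(sm, q); sm$s }
    p <- project(map, s)
    r <- reward(p, s)
    ek <- effective_rate(cfg$eta, r)
    state <- update_components(state, s - state$mean, ek)
    state <- regularize_variance(state, cfg$noise_var)
    if (cfg$mode == "coadapt" && cfg$gamma > 0) map <- adapt_step(map, s, cfg$gamma)
  }
  list(state = state, map = map)
}

# dispatch a config to the matching engine entry point
run_engine <- function(cfg, map, state) {
  if (cfg$mode == "coadapt") run_coadaptation(cfg, map, state)
  else run_user_learning(cfg, map, state)
}

# top-2 orthonormal basis of a state's sampling covariance
state_top2 <- function(state) {
  eigen(state_covariance(state), symmetric = TRUE)$vectors[, 1:2, drop = FALSE]
}
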