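#' Generative user model state
#'
#' The simulated interface user is a non-stationary multivariate Gaussian
#' generative process. Its covariance is represented through scaled eigenvector
#' estimates \eqn{w_i = \lambda_i v_i} (one per column of \code{components}),
#' tracked sample-by-sample by reward-weighted incremental PCA, plus the
#' regularized eigenvalue spectrum actually used for sampling. The initial
#' spectrum is recorded at construction: the variance-regularization step keeps
#' the summed variance of the first \code{task_dim} components equal to its
#' initial value and the first-\code{task_dim} variance fraction from falling
#' below its initial value, preventing the vanishing-variance degeneracy of
#' pure recursive updating.
#'
#' @param components numeric \code{n x n} matrix, column \code{i} holding the
#'   scaled eigenvector estimate \eqn{w_i}.
#' @param task_dim number of task dimensions \eqn{m} (the device dimension).
#' @param mean numeric n-vector \eqn{\mu}; defaults to zero (the simulation
#'   modes use a centered model; playback re-estimates the mean).
#' @param lambda_reg regularized spectrum used for sampling; defaults to the
#'   column norms of \code{components}.
#' @param initial_spectrum reference spectrum for the regularization
#'   constraints; defaults to \code{lambda_reg} at construction.
#' @return An object of class \code{generative_state}.
#' @export
generative_state <- function(components, task_dim, mean = NULL,
                             lambda_reg = NULL, initial_spectrum = NULL) {
  components <- as.matrix(components)
  n <- nrow(components)
  if (ncol(components) != n) stop("components must be an n x n matrix")
  if (task_dim >= n || task_dim < 1) stop("task_dim must satisfy 1 <= m < n")
  nrm <- sqrt(colSums(components^2))
  if (any(nrm < 1e-12)) stop("all component estimates must have norm >= 1e-12")
  if (is.null(mean)) mean <- numeric(n)
  if (length(mean) != n) stop("mean must have length n")
  if (is.null(lambda_reg)) lambda_reg <- nrm
  if (is.null(initial_spectrum)) initial_spectrum <- lambda_reg
  if (any(lambda_reg < 0) || any(initial_spectrum < 0))
    stop("spectra must be non-negative")
  structure(
    list(mean = as.numeric(mean), components = unname(components),
         lambda_reg = as.numeric(lambda_reg),
         initial_spectrum = as.numeric(initial_spectrum),
         task_dim = as.integer(task_dim)),
    class = "generative_state"
  )
}

#' @export
print.generative_state <- function(x, ...) {
  n <- length(x$mean)
  cat("<generative_state> n =", n, ", task_dim =", x$task_dim, "\n")
  cat("regularized spectrum:", format(x$lambda_reg, digits = 4), "\n")
  cat("planarity:", format(planarity(x$lambda_reg), digits = 4), "\n")
  invisible(x)
}

#' Eigenvalues and eigenvectors of a generative state
#'
#' Eigenvalue estimates are the norms of the scaled components,
#' \eqn{\lambda_i = \|w_i\|}; eigenvector estimates are the unit-normalized
#' columns \eqn{v_i = w_i / \|w_i\|}. Components keep their fixed update order
#' (the deflation order of the incremental PCA); metrics that need a sorted
#' spectrum sort on their own.
#'
#' @param state a \code{\link{generative_state}}.
#' @return \code{state_eigenvalues}: numeric n-vector; \code{state_eigenvectors}:
#'   \code{n x n} matrix of unit columns.
#' @export
state_eigenvalues <- function(state) {
  stopifnot(inherits(state, "generative_state"))
  sqrt(colSums(state$components^2))
}

#' @rdname state_eigenvalues
#' @export
state_eigenvectors <- function(state) {
  stopifnot(inherits(state, "generative_state"))
  sweep(state$components, 2, sqrt(colSums(state$components^2)), "/")
}

#' Current covariance of the generative model
#'
#' Rebuilds \eqn{\Sigma = V \hat\Lambda V^T} from the unit eigenvector
#' estimates and the regularized spectrum. Always symmetric positive
#' semi-definite.
#'
#' @param state a \code{\link{generative_state}}.
#' @return Symmetric \code{n x n} matrix.
#' @export
state_covariance <- function(state) {
  V <- state_eigenvectors(state)
  S <- V %*% (state$lambda_reg * t(V))
  (S + t(S)) / 2
}

#' Draw one action from the generative model
#'
#' Samples \eqn{q \sim N(\mu, \Sigma)} with \eqn{\Sigma} rebuilt from the
#' current eigenstructure, as \eqn{q = \mu + V \hat\Lambda^{1/2} z} with
#' \eqn{z} standard normal. Consumes exactly \code{n} draws from R's RNG
#' stream (the same layout the compiled simulation loop uses), so runs are
#' reproducible under \code{set.seed}.
#'
#' @param state a \code{\link{generative_state}}.
#' @return Numeric n-vector.
#' @export
draw_action <- function(state) {
  stopifnot(inherits(state, "generative_state"))
  V <- state_eigenvectors(state)
  state$mean + drop(V %*% (sqrt(state$lambda_reg) * rnorm(length(state$mean))))
}

#' Autoregressive action smoother
#'
#' First-order autoregressive exponentially weighted moving average turning
#' independent draws into a statistically dependent trajectory:
#' \eqn{s_k = \alpha s_{k-1} + \beta q_k}, initialized with \eqn{s_0 = q_0}.
#' The defaults \eqn{\alpha = 0.99}, \eqn{\beta = 0.15} reproduce the
#' autocorrelation of upper-limb inertial sensor recordings at a nominal
#' 50 Hz sampling rate.
#'
#' @param q0 initial draw \eqn{q_0} (sets \eqn{s_0}).
#' @param alpha AR coefficient, \eqn{0 \le \alpha < 1}.
#' @param beta input gain, \eqn{\beta > 0}.
#' @return An object of class \code{smoothing_state} with fields \code{s},
#'   \code{alpha}, \code{beta}.
#' @export
smoothing_state <- function(q0, alpha = 0.99, beta = 0.15) {
  if (alpha < 0 || alpha >= 1) stop("alpha must satisfy 0 <= alpha < 1")
  if (beta <= 0) stop("beta must be positive")
  structure(list(s = as.numeric(q0), alpha = alpha, beta = beta),
            class = "smoothing_state")
}

#' @rdname smoothing_state
#' @param sm a \code{smoothing_state}.
#' @param q new independent draw.
#' @return \code{smooth_step}: the updated \code{smoothing_state}; the new
#'   smoothed signal is in its \code{s} field.
#' @export
smooth_step <- function(sm, q) {
  stopifnot(inherits(sm, "smoothing_state"))
  q <- as.numeric(q)
  if (length(q) != length(sm$s)) stop("dimension mismatch in smooth_step")
  sm$s <- sm$alpha * sm$s + sm$beta * q
  sm
}

#' Reward of an action given its feedback
#'
#' The reward is the fraction of signal power transmitted through the map,
#' \eqn{r = \|p\|^2 / \|s\|^2}. For \eqn{p = Bs} with orthonormal-row \eqn{B}
#' this lies in \eqn{[0, 1]}: 1 when the action is entirely in the potent
#' space, 0 when it is entirely in the null space. A zero-norm action is
#' assigned zero reward (no feedback, no reinforcement).
#'
#' @param p feedback (m-vector).
#' @param s action / control signal (n-vector).
#' @return Scalar reward.
#' @export
reward <- function(p, s) {
  ss <- sum(as.numeric(s)^2)
  if (ss == 0) return(0)
  sum(as.numeric(p)^2) / ss
}

#' Reward-modulated effective learning rate
#'
#' \eqn{\eta_k = \eta \cdot r_k}: use-dependent learning with the update
#' magnitude scaled by the reward, so highly rewarded actions are reinforced
#' and unrewarded ones leave the model (almost) untouched. Bounded in
#' \eqn{[0, \eta]}.
#'
#' @param eta base learning rate, recommended within \eqn{[10^{-5}, 10^{-1}]}
#'   for convergence and stability.
#' @param r reward in \eqn{[0, 1]}.
#' @return Scalar effective rate.
#' @export
effective_rate <- function(eta, r) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < -1e-12 || r > 1 + 1e-12)
    stop("reward must be a single value in [0, 1], got ", r)
  eta * min(max(r, 0), 1)
}

#' Incremental update of the mean estimate
#'
#' Exponential smoothing \eqn{\mu \leftarrow (1-\eta_k)\mu + \eta_k q}. Active
#' only in playback mode (the simulation modes use a centered model).
#'
#' @param state a \code{\link{generative_state}}.
#' @param q observed action.
#' @param eta_k effective learning rate in \eqn{[0, 1]}.
#' @return Updated state.
#' @export
update_mean <- function(state, q, eta_k) {
  stopifnot(inherits(state, "generative_state"))
  state$mean <- (1 - eta_k) * state$mean + eta_k * as.numeric(q)
  state
}

#' Reward-weighted incremental update of the covariance eigenstructure
#'
#' One CCIPCA sweep over all \eqn{n} scaled components:
#' \eqn{w_i \leftarrow (1-\eta_k) w_i + \eta_k (x_i x_i^T w_i)/\|w_i\|}, with
#' \eqn{x_1 = x} and \eqn{x_{i+1} = x_i - (x_i^T v_i) v_i} (residual
#' deflation, using the freshly updated direction). \code{x} must already be
#' mean-centered.
#'
#' @param state a \code{\link{generative_state}}.
#' @param x mean-centered input (n-vector).
#' @param eta_k effective learning rate in \eqn{[0, 1]}.
#' @return Updated state (eigenvalues/eigenvectors re-derived from the new
#'   scaled components on demand).
#' @export
update_components <- function(state, x, eta_k) {
  stopifnot(inherits(state, "generative_state"))
  state$components <- ccipca_sweep(state$components, x, eta_k)
  state
}

#' Variance regularization
#'
#' Computes the regularized spectrum \eqn{\hat\Lambda = diag(|\lambda +
#' \lambda_C + z|)} from the current eigenvalue estimates
#' \eqn{\lambda_i = \|w_i\|}, where \eqn{z} is i.i.d. zero-mean Gaussian noise
#' of variance \code{noise_var} and \eqn{\lambda_C} is a corrective term that
#' (a) restores each of the first \eqn{m} components to its initial vigor
#' (\eqn{\lambda_{C,j} = \lambda_{j,0} - \lambda_j} for \eqn{j \le m}), so the
#' summed task-dimension variance is conserved exactly and the model cannot
#' collapse onto fewer than \eqn{m} task dimensions, and (b) keeps the
#' first-\eqn{m} variance fraction at or above its initial value
#' (multiplicative shrink of the trailing components, factor clipped at 1).
#' Consumes \code{n} normal draws from the RNG stream (also when
#' \code{noise_var = 0}, so the stream layout is independent of the noise
#' setting).
#'
#' @param state a \code{\link{generative_state}}.
#' @param noise_var variance of the additive noise term (default \code{1e-4}).
#' @return Updated state with a new \code{lambda_reg}; all entries
#'   non-negative.
#' @export
regularize_variance <- function(state, noise_var = 1e-4) {
  stopifnot(inherits(state, "generative_state"))
  n <- length(state$mean)
  m <- state$task_dim
  lam <- state_eigenvalues(state)
  z <- sqrt(noise_var) * rnorm(n)
  lam0 <- state$initial_spectrum
  S0m <- sum(lam0[seq_len(m)])
  f0 <- S0m / sum(lam0)
  t <- lam + z
  t[seq_len(m)] <- lam0[seq_len(m)] + z[seq_len(m)]
  for (it in 1:16) {
    d <- (S0m - sum(t[seq_len(m)])) / m
    t[seq_len(m)] <- t[seq_len(m)] + d
    t <- abs(t)
    if (abs(sum(t[seq_len(m)]) - S0m) < 1e-12) break
  }
  tail_idx <- seq.int(m + 1, n)
  Stail <- sum(t[tail_idx])
  Smax <- S0m * (1 - f0) / f0
  if (Stail > Smax && Stail > 0) t[tail_idx] <- t[tail_idx] * (Smax / Stail)
  state$lambda_reg <- t
  state
}

#' Expected reward of the current generative model under a map
#'
#' Closed-form expectation of the per-sample reward over the generative
#' distribution: \eqn{[tr(B\Sigma B^T) + tr(B\mu\mu^T B^T)] / [tr(\Sigma) +
#' tr(\mu\mu^T)]}, reducing to \eqn{tr(B\Sigma B^T)/tr(\Sigma)} for a centered
#' model. Lies in \eqn{[0, 1]} for orthonormal-row maps and is maximized when
#' the model's variance lies entirely in the map's potent space.
#'
#' @param map an \code{\link{interface_map}}.
#' @param state a \code{\link{generative_state}}.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
expected_reward <- function(map, state) {
  stopifnot(inherits(map, "interface_map"), inherits(state, "generative_state"))
  S <- state_covariance(state)
  mu <- state$mean
  denom <- sum(diag(S)) + sum(mu^2)
  if (denom == 0) stop("expected reward undefined: zero total power")
  BS <- map$rows %*% S
  Bmu <- drop(map$rows %*% mu)
  (sum(BS * map$rows) + sum(Bmu^2)) / denom
}

#' Time constant of the exponential learning filter
#'
#' The recursive estimators are first-order exponential filters with time
#' constant \eqn{\tau = -T / \ln(1 - \eta)}: the number of samples over which
#' about 63\% of a step change is incorporated. For small \eqn{\eta},
#' \eqn{\tau \approx T/\eta}.
#'
#' @param eta learning rate in \eqn{(0, 1)}.
#' @param T sampling interval (default 1 iteration).
#' @return Time constant in the units of \code{T}.
#' @export
time_constant <- function(eta, T = 1) {
  if (!is.numeric(eta) || any(eta <= 0) || any(eta >= 1))
    stop("eta must lie strictly inside (0, 1)")
  if (T <= 0) stop("T must be positive")
  -T / log(1 - eta)
}

#' Write / read a generative state as plain text
#'
#' Plain-text blocks (mean, regularized and initial spectra, component matrix)
#' under a one-line header; lossless round trip at full double precision.
#'
#' @param state a \code{\link{generative_state}}.
#' @param path file path.
#' @export
write_generative_state <- function(state, path) {
  stopifnot(inherits(state, "generative_state"))
  n <- length(state$mean)
  fmt <- function(x) paste(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                           collapse = " ")
  lines <- c(
    paste("coadapt-state", n, state$task_dim),
    fmt(state$mean),
    fmt(state$lambda_reg),
    fmt(state$initial_spectrum),
    apply(state$components, 1, fmt)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_generative_state
#' @export
read_generative_state <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\\s+")[[1]]
  if (length(header) != 3 || header[1] != "coadapt-state")
    stop("not a generative state file: ", path)
  n <- as.integer(header[2]); m <- as.integer(header[3])
  num <- function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  comp <- t(vapply(lines[4 + seq_len(n)], num, numeric(n), USE.NAMES = FALSE))
  generative_state(comp, task_dim = m, mean = num(lines[2]),
                   lambda_reg = num(lines[3]), initial_spectrum = num(lines[4]))
}
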