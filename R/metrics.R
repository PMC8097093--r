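#' Planarity of a variance spectrum
#'
#' Fraction of total variance carried by the two largest eigenvalues,
#' \eqn{(\lambda_{(1)} + \lambda_{(2)}) / \sum_i \lambda_i}. A 2-D
#' task-alignment index in \eqn{(0, 1]}: users controlling a 2-D device are
#' expected to concentrate their action variance on a plane. Eigenvalues are
#' sorted internally, so component order is irrelevant, and the index is
#' invariant to overall scaling of the spectrum.
#'
#' @param eigenvalues numeric vector of non-negative variances (length >= 2).
#' @return Scalar planarity.
#' @export
planarity <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 2) stop("planarity needs at least two eigenvalues")
  if (any(ev < 0)) stop("eigenvalues must be non-negative")
  tot <- sum(ev)
  if (tot <= 0) stop("planarity undefined for an all-zero spectrum")
  ev <- sort(ev, decreasing = TRUE)
  (ev[1] + ev[2]) / tot
}

#' Largest principal angle between the map and a 2-D subspace
#'
#' Angular distance between the subspace spanned by the map's rows and the
#' span of two orthonormal directions (typically the top-2 eigenvectors of the
#' user covariance). Computed as \eqn{\arccos} of the smallest singular value
#' of the matrix of inner products between the two orthonormal bases: 0 deg
#' for identical spans, 90 deg for orthogonal ones. Symmetric in its
#' arguments and invariant to orthonormal re-parameterization of either basis.
#'
#' @param map an \code{\link{interface_map}}, or a matrix whose rows are an
#'   orthonormal basis of the first subspace.
#' @param basis2 \code{n x 2} matrix with orthonormal columns.
#' @return Angle in degrees, in \eqn{[0, 90]}.
#' @export
subspace_angle <- function(map, basis2) {
  B <- if (inherits(map, "interface_map")) map$rows else as.matrix(map)
  basis2 <- as.matrix(basis2)
  if (ncol(B) != nrow(basis2)) stop("dimension mismatch between subspaces")
  G <- crossprod(basis2)
  if (max(abs(G - diag(ncol(basis2)))) > 1e-9)
    stop("basis2 columns must be orthonormal (within 1e-9)")
  GB <- tcrossprod(B)
  if (max(abs(GB - diag(nrow(B)))) > 1e-9)
    stop("first basis rows must be orthonormal (within 1e-9)")
  sv <- svd(B %*% basis2, nu = 0, nv = 0)$d
  acos(min(max(min(sv), -1), 1)) * 180 / pi
}

#' Variance accounted for by the interface map
#'
#' Percentage of the user's covariance transmitted through the map,
#' \eqn{tr(B \Sigma B^T)/tr(\Sigma) \cdot 100}. A control-efficiency measure in
#' \eqn{[0, 100]} for orthonormal-row maps; for a centered model it equals 100
#' times the expected per-sample reward.
#'
#' @param map an \code{\link{interface_map}}.
#' @param covariance symmetric PSD \code{n x n} matrix with positive trace.
#' @return Percentage in \eqn{[0, 100]}.
#' @export
vaf <- function(map, covariance) {
  stopifnot(inherits(map, "interface_map"))
  covariance <- as.matrix(covariance)
  tot <- sum(diag(covariance))
  if (tot <= 0) stop("vaf undefined for a zero-trace covariance")
  sum((map$rows %*% covariance) * map$rows) / tot * 100
}

#' Exponential convergence fit of a learning trace
#'
#' Least-squares fit of the single-exponential relaxation
#' \eqn{\theta(k) = \theta_\infty + (\theta_0 - \theta_\infty) e^{-k/\tau}}
#' to a metric trace (typically the Subspace Angle over iterations). The time
#' constant \eqn{\tau} is the number of iterations for 63\% of the total
#' improvement. \eqn{\tau} is initialized from the 63\%-crossing of a
#' lightly smoothed copy of the trace and bounded in \eqn{[1, 10 K]}; the
#' goodness of fit \eqn{R^2} is computed on the raw trace. Fits are reported
#' with \code{converged = FALSE} (never an error) when the optimizer fails or
#' the trace is degenerate; callers apply the \eqn{R^2 \ge 0.40} inclusion
#' gate when aggregating.
#'
#' @param series numeric trace of the metric (length >= 10).
#' @param iterations iteration index of each sample (default
#'   \code{seq_along(series)}; pass the recorded iterations when the trace is
#'   thinned so \eqn{\tau} is in true iterations).
#' @return An object of class \code{convergence_fit}: list with \code{tau},
#'   \code{theta0}, \code{theta_inf}, \code{r_squared}, \code{converged}.
#' @export
fit_convergence <- function(series, iterations = NULL) {
  y <- as.numeric(series)
  if (length(y) < 10) stop("convergence fit needs at least 10 samples")
  k <- if (is.null(iterations)) seq_along(y) else as.numeric(iterations)
  if (length(k) != length(y)) stop("iterations and series lengths differ")
  K <- max(k)
  not_conv <- structure(list(tau = NA_real_, theta0 = y[1], theta_inf = y[length(y)],
                             r_squared = NA_real_, converged = FALSE),
                        class = "convergence_fit")
  if (stats::sd(y) == 0) return(not_conv)

  # tau start value from the 63% crossing of a smoothed copy
  w <- max(1, floor(length(y) / 50))
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  target <- ys[1] + 0.63 * (ys[length(ys)] - ys[1])
  cross <- if (ys[length(ys)] < ys[1]) which(ys <= target) else which(ys >= target)
  tau0 <- if (length(cross)) max(k[cross[1]], 1) else K / 3
  tau0 <- min(max(tau0, 1), 10 * K)

  df <- data.frame(k = k, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ th_inf + (th0 - th_inf) * exp(-k / tau), data = df,
      start = list(th0 = ys[1], th_inf = ys[length(ys)], tau = tau0),
      lower = c(-Inf, -Inf, 1), upper = c(Inf, Inf, 10 * K),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(not_conv)
  cf <- stats::coef(fit)
  res <- y - stats::predict(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(tau = unname(cf["tau"]), theta0 = unname(cf["th0"]),
                 theta_inf = unname(cf["th_inf"]), r_squared = r2,
                 converged = TRUE),
            class = "convergence_fit")
}

#' @export
print.convergence_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<convergence_fit> tau = %.1f, theta0 = %.2f, theta_inf = %.2f, R^2 = %.3f\n",
                x$tau, x$theta0, x$theta_inf, x$r_squared))
  else cat("<convergence_fit> not converged\n")
  invisible(x)
}

#' Sliding-window covariance eigenstructure of a sequence
#'
#' Sample covariance eigendecomposition over a sliding window (default 3000
#' samples, i.e. 60 s at 50 Hz), as used to estimate the time course of the
#' covariance of recorded sensor sequences. Each window yields the descending
#' eigenvalues and the top-2 orthonormal basis, ready to feed
#' \code{\link{planarity}}, \code{\link{subspace_angle}} and \code{\link{vaf}}.
#'
#' @param sequence numeric matrix, samples x channels.
#' @param window window length in samples (default 3000).
#' @param stride step between window starts (default \code{window}).
#' @return List with \code{start} (window start indices), \code{eigenvalues}
#'   (windows x n, descending), \code{basis2} (list of \code{n x 2} matrices)
#'   and \code{covariances} (list of \code{n x n} matrices).
#' @export
sliding_covariance <- function(sequence, window = 3000, stride = window) {
  X <- as.matrix(sequence)
  if (nrow(X) < window)
    stop("sequence has ", nrow(X), " samples, shorter than the window (", window, ")")
  starts <- seq.int(1, nrow(X) - window + 1, by = stride)
  n <- ncol(X)
  evals <- matrix(NA_real_, length(starts), n)
  basis2 <- vector("list", length(starts))
  covs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    S <- stats::cov(X[starts[i] + 0:(window - 1), , drop = FALSE])
    e <- eigen(S, symmetric = TRUE)
    evals[i, ] <- pmax(e$values, 0)
    basis2[[i]] <- e$vectors[, 1:2, drop = FALSE]
    covs[[i]] <- S
  }
  list(start = starts, eigenvalues = evals, basis2 = basis2, covariances = covs)
}
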