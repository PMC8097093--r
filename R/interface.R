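#' Linear orthogonal interface map
#'
#' Constructs the interface map \eqn{B}: a linear dimensionality-reducing map
#' from \eqn{n}-dimensional body signals to an \eqn{m}-dimensional device
#' command (\eqn{m < n}) with mutually orthogonal unit-norm rows. The object
#' keeps two coupled representations: \code{scaled}, the internal incremental-PCA
#' component estimates \eqn{\tilde b_i} whose norms track the captured variance,
#' and \code{rows}, the exposed orthonormal rows obtained by Gram-Schmidt
#' orthonormalization of \code{scaled} (recomputed after every adaptive update).
#' For orthonormal rows the Moore-Penrose pseudoinverse is simply \eqn{B^T},
#' which is what \code{\link{null_residual}} exploits.
#'
#' @param scaled numeric matrix, \code{m x n}: one scaled component estimate per
#'   row. Rows need not be orthogonal; the exposed map is their Gram-Schmidt
#'   orthonormalization in row order.
#' @return An object of class \code{interface_map} with fields \code{n_in},
#'   \code{n_out}, \code{rows} (\code{m x n}, orthonormal rows) and
#'   \code{scaled} (\code{m x n}).
#' @examples
#' B <- interface_map(rbind(c(3, 0, 0, 0), c(1, 1, 0, 0)))
#' B$rows            # e1, e2
#' project(B, c(1, 2, 3, 4))
#' @export
interface_map <- function(scaled) {
  scaled <- as.matrix(scaled)
  if (!is.numeric(scaled)) stop("scaled estimates must be numeric")
  m <- nrow(scaled)
  n <- ncol(scaled)
  if (m >= n) stop("interface map requires m < n (got m = ", m, ", n = ", n, ")")
  map <- structure(
    list(n_in = n, n_out = m, scaled = unname(scaled), rows = NULL),
    class = "interface_map"
  )
  orthonormalize(map)
}

#' @export
print.interface_map <- function(x, ...) {
  cat("<interface_map> ", x$n_out, " x ", x$n_in,
      " (orthonormal rows over scaled CCIPCA estimates)\n", sep = "")
  cat("captured-variance scales:", format(sqrt(rowSums(x$scaled^2)), digits = 4), "\n")
  invisible(x)
}

#' Re-orthonormalize the exposed rows of an interface map
#'
#' Gram-Schmidt orthonormalization of the scaled component estimates, in
#' component order. Called internally after every \code{\link{adapt_step}} so
#' that the exposed map always satisfies the orthogonal-transformation
#' assumption the reward bound relies on.
#'
#' @param map an \code{\link{interface_map}}.
#' @return The map with \code{rows} recomputed.
#' @export
orthonormalize <- function(map) {
  stopifnot(inherits(map, "interface_map"))
  U <- t(map$scaled)                     # n x m, columns = component estimates
  for (j in seq_len(ncol(U))) {
    if (j > 1) {
      for (i in seq_len(j - 1)) U[, j] <- U[, j] - sum(U[, j] * U[, i]) * U[, i]
    }
    nn <- sqrt(sum(U[, j]^2))
    if (nn < 1e-10)
      stop("degenerate map: component ", j, " is (near-)linearly dependent")
    U[, j] <- U[, j] / nn
  }
  map$rows <- t(U)
  map
}

#' Project a body signal through the interface map
#'
#' Computes the device command \eqn{p = B s}. With orthonormal rows this is an
#' orthogonal projection onto the map's potent space expressed in latent
#' coordinates, so \eqn{\|p\| \le \|s\|}.
#'
#' @param map an \code{\link{interface_map}}.
#' @param s numeric vector of length \code{map$n_in}.
#' @return Numeric vector of length \code{map$n_out}.
#' @export
project <- function(map, s) {
  stopifnot(inherits(map, "interface_map"))
  s <- as.numeric(s)
  if (length(s) != map$n_in)
    stop("input has length ", length(s), ", expected ", map$n_in)
  drop(map$rows %*% s)
}

#' Null-space residual of a body signal
#'
#' Returns \eqn{q - B^T(Bq)}, the component of \code{q} in the null space of
#' the map: the part of the action that produces no device motion. The result
#' satisfies \eqn{B \cdot residual = 0} and the Pythagorean split
#' \eqn{\|q\|^2 = \|Bq\|^2 + \|residual\|^2}.
#'
#' @inheritParams project
#' @param q numeric vector of length \code{map$n_in}.
#' @return Numeric vector of length \code{map$n_in}.
#' @export
null_residual <- function(map, q) {
  stopifnot(inherits(map, "interface_map"))
  q <- as.numeric(q)
  if (length(q) != map$n_in)
    stop("input has length ", length(q), ", expected ", map$n_in)
  q - drop(crossprod(map$rows, map$rows %*% q))
}

#' One unsupervised adaptive update of the interface map
#'
#' Candid covariance-free incremental PCA (CCIPCA) step on the scaled component
#' estimates: \eqn{\tilde b \leftarrow (1-\gamma)\tilde b + \gamma\, (x x^T
#' \tilde b)/\|\tilde b\|}, where \eqn{x} is the observed (zero-mean) user
#' signal for the first component and its residual after deflating previously
#' updated components for the following ones. The exposed rows are
#' re-orthonormalized afterwards. With \code{gamma = 0} the map is returned
#' bit-identical.
#'
#' @inheritParams project
#' @param s numeric vector of length \code{map$n_in}, assumed zero-mean.
#' @param gamma adaptation rate in \eqn{[0, 1]}.
#' @return The updated \code{\link{interface_map}}.
#' @export
adapt_step <- function(map, s, gamma) {
  stopifnot(inherits(map, "interface_map"))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1)
    stop("gamma must be a single value in [0, 1]")
  s <- as.numeric(s)
  if (length(s) != map$n_in)
    stop("input has length ", length(s), ", expected ", map$n_in)
  if (gamma == 0) return(map)
  map$scaled <- t(ccipca_sweep(t(map$scaled), s, gamma))
  orthonormalize(map)
}

# Shared CCIPCA sweep over the columns of W (n x k), deflating with the
# freshly updated unit direction; used by both the interface and the user model.
ccipca_sweep <- function(W, x, rate) {
  x <- as.numeric(x)
  for (i in seq_len(ncol(W))) {
    nw <- sqrt(sum(W[, i]^2))
    if (nw < 1e-12)
      stop("degenerate component estimate ", i, ": norm below 1e-12")
    W[, i] <- (1 - rate) * W[, i] + rate * (sum(x * W[, i]) / nw) * x
    nn <- sqrt(sum(W[, i]^2))
    if (nn < 1e-12)
      stop("degenerate component estimate ", i, ": norm below 1e-12")
    v <- W[, i] / nn
    x <- x - sum(x * v) * v
  }
  W
}

#' Write / read an interface map as plain text
#'
#' Whitespace-delimited matrix of the scaled component estimates with a one-line
#' header \code{"coadapt-map n m"}. The round trip is lossless to full double
#' precision (values are written with 17 significant digits).
#'
#' @param map an \code{\link{interface_map}}.
#' @param path file path.
#' @return \code{write_interface_map} returns \code{path} invisibly;
#'   \code{read_interface_map} returns an \code{\link{interface_map}}.
#' @export
write_interface_map <- function(map, path) {
  stopifnot(inherits(map, "interface_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("coadapt-map", map$n_in, map$n_out), con)
  write.table(format(map$scaled, digits = 17, scientific = TRUE, trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_interface_map
#' @export
read_interface_map <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\\s+")[[1]]
  if (length(header) != 3 || header[1] != "coadapt-map")
    stop("not an interface map file: ", path)
  n <- as.integer(header[2]); m <- as.integer(header[3])
  M <- as.matrix(read.table(path, skip = 1))
  if (nrow(M) != m || ncol(M) != n)
    stop("map file body is ", nrow(M), " x ", ncol(M),
         " but header declares ", m, " x ", n)
  interface_map(M)
}
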