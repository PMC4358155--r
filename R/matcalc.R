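#' Stack the columns of a matrix into a vector
#'
#' The vec operator stacks the columns of an \code{n x m} matrix into a
#' single \code{nm x 1} vector, in column-major order.  All Jacobians and
#' Hessians in this package are laid out in vec order: the matrix entry
#' \eqn{a_{ij}} of an \code{n x n} matrix occupies vec position
#' \eqn{k = (j - 1) n + i} (1-based).
#'
#' @param M a numeric matrix with finite entries.
#' @return a numeric vector of length \code{nrow(M) * ncol(M)}.
#' @seealso [unvec()], [vec_index()], [commutation_matrix()]
#' @examples
#' vec(matrix(1:4, 2, 2))
#' @export
vec <- function(M) {
  M <- as.matrix(M)
  if (!is.numeric(M) || any(!is.finite(M)))
    stop("vec(): matrix must be numeric with finite entries")
  dim(M) <- NULL
  M
}

#' Invert the vec operator
#'
#' @param x numeric vector of length \code{n * m}.
#' @param n,m target dimensions; \code{m} defaults to \code{n} (square).
#' @return the \code{n x m} matrix \code{M} with \code{vec(M) == x}.
#' @export
unvec <- function(x, n, m = n) {
  if (length(x) != n * m)
    stop("unvec(): length(x) != n * m")
  matrix(x, nrow = n, ncol = m)
}

#' Map matrix subscripts to vec positions and back
#'
#' Column-major convention: entry \eqn{(i, j)} of an \code{n x n} matrix
#' sits at vec position \eqn{k = (j - 1) n + i}.
#'
#' @param i,j 1-based matrix subscripts (vectorised).
#' @param k 1-based vec positions (vectorised).
#' @param n matrix dimension.
#' @return \code{vec_index()} returns positions \code{k};
#'   \code{vec_subscripts()} returns a two-column matrix of \code{(i, j)}.
#' @export
vec_index <- function(i, j, n) {
  stopifnot(all(i >= 1), all(i <= n), all(j >= 1), all(j <= n))
  (j - 1L) * n + i
}

#' @rdname vec_index
#' @export
vec_subscripts <- function(k, n) {
  stopifnot(all(k >= 1), all(k <= n * n))
  k <- as.integer(k - 1L)
  cbind(i = k %% n + 1L, j = k %/% n + 1L)
}

#' Commutation (vec-permutation) matrix
#'
#' Returns the \code{mn x mn} permutation matrix \eqn{K_{m,n}} satisfying
#' \eqn{K_{m,n} \mathrm{vec}(X) = \mathrm{vec}(X^T)} for any
#' \code{m x n} matrix \code{X}.  Built as a sparse permutation so that
#' large stage counts stay cheap; use \code{sparse = FALSE} (or
#' \code{as.matrix()}) to densify.
#'
#' @param m,n positive integer dimensions.
#' @param sparse logical; return a sparse \pkg{Matrix} permutation
#'   (default) or a dense base matrix.
#' @return an \code{mn x mn} 0/1 permutation matrix.
#' @examples
#' K <- commutation_matrix(2, 3)
#' X <- matrix(rnorm(6), 2, 3)
#' all.equal(as.numeric(K %*% vec(X)), vec(t(X)))
#' @export
commutation_matrix <- function(m, n = m, sparse = TRUE) {
  if (length(m) != 1 || length(n) != 1 || m < 1 || n < 1 ||
      m != round(m) || n != round(n))
    stop("commutation_matrix(): m and n must be positive integers")
  m <- as.integer(m); n <- as.integer(n)
  # vec(X)[k] with k = (j-1)m + i maps to vec(X')[(i-1)n + j]
  k <- seq_len(m * n)
  i <- (k - 1L) %% m + 1L
  j <- (k - 1L) %/% m + 1L
  rows <- (i - 1L) * n + j
  K <- Matrix::sparseMatrix(i = rows, j = k, x = 1, dims = c(m * n, m * n))
  if (sparse) K else as.matrix(K)
}

#' Roth's identity: vec of a triple product
#'
#' Computes \eqn{\mathrm{vec}(XYZ)}.  Roth's theorem states that
#' \eqn{\mathrm{vec}(XYZ) = (Z^T \otimes X)\,\mathrm{vec}(Y)}; the two
#' sides of this identity are used throughout the Hessian derivations and
#' in the package's tests.
#'
#' @param X,Y,Z conformable numeric matrices (vectors are treated as
#'   single-column matrices, scalars as 1 x 1).
#' @return the vector \code{vec(X \%*\% Y \%*\% Z)}.
#' @export
roth_reshape <- function(X, Y, Z) {
  X <- as.matrix(X); Y <- as.matrix(Y); Z <- as.matrix(Z)
  if (ncol(X) != nrow(Y) || ncol(Y) != nrow(Z))
    stop("roth_reshape(): dimensions not conformable for X %*% Y %*% Z")
  vec(X %*% Y %*% Z)
}

# symmetrize after asserting near-symmetry; used by every Hessian builder
.symmetrize <- function(H, label = "Hessian", tol = 1e-8) {
  asym <- max(abs(H - t(H)))
  scale <- max(abs(H))
  if (scale > 0 && asym > tol * scale)
    warning(sprintf("%s asymmetry %.3g relative to max |entry|; symmetrizing",
                    label, asym / scale))
  structure((H + t(H)) / 2, asym = if (scale > 0) asym / scale else 0)
}
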