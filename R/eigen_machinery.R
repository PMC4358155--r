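#' Dominant eigensystem of a projection matrix
#'
#' Computes the dominant eigenvalue \eqn{\lambda} and the associated
#' right and left eigenvectors \code{w} and \code{v} of a nonnegative
#' projection matrix, under the scaling conventions used throughout the
#' package:
#' \deqn{e^T w = 1, \qquad v^T w = 1,}
#' where \code{e} is a vector of ones.  With this scaling the first
#' derivative of \eqn{\lambda} with respect to entry \eqn{a_{ij}} is the
#' classical sensitivity \eqn{v_i w_j}, with no denominator.
#'
#' The dominant eigenvalue must be real and simple (strictly dominant in
#' modulus).  A dominant eigenvalue closer than \code{tol_simple}
#' (relative) to the subdominant modulus triggers an error, because the
#' eigenvector derivatives — and hence every Hessian — are undefined at a
#' crossing.  A reducible matrix produces a warning and the computation
#' proceeds if the dominant eigenvalue is still simple and real.
#'
#' @param M a [stage_matrix()] or a plain nonnegative square matrix.
#' @param tol_simple relative tolerance below which the spectral gap
#'   \eqn{|\lambda_1| - |\lambda_2|} is declared zero.
#' @return an object of class \code{"eigensystem"}: a list with elements
#'   \code{lambda}, \code{w}, \code{v}, \code{gap} (the modulus ratio
#'   \eqn{|\lambda_2| / |\lambda_1|}), \code{A} and \code{n}.
#' @examples
#' es <- dominant_eigensystem(matrix(c(0, 0.5, 2, 0), 2, 2))
#' es$lambda  # 1
#' @export
dominant_eigensystem <- function(M, tol_simple = 1e-8) {
  sm <- as_stage_matrix(M)
  A <- sm$A
  n <- sm$n
  if (n == 1) {
    out <- list(lambda = A[1, 1], w = 1, v = 1, gap = 0, A = A, n = 1L)
    class(out) <- "eigensystem"
    return(out)
  }
  if (!.is_irreducible(A))
    warning("projection matrix is reducible; proceeding (dominant eigenvalue still simple and real)")
  eA <- eigen(A)
  mods <- Mod(eA$values)
  # Perron root of a nonnegative matrix: real, equal to the spectral
  # radius, and maximal in real part
  i1 <- which.max(Re(eA$values))
  lam <- eA$values[i1]
  if (abs(Im(lam)) > tol_simple * max(mods))
    stop("dominant eigenvalue is complex; the matrix violates the real, simple dominant-eigenvalue assumption")
  lam <- Re(lam)
  if (lam <= 0)
    stop("dominant eigenvalue is not positive")
  gap <- if (n > 1) max(mods[-i1]) / mods[i1] else 0
  # eigenvector derivatives require algebraic simplicity (an isolated
  # eigenvalue in the complex plane); strict modulus dominance is an
  # ergodicity property and only merits a warning when absent
  if (min(Mod(eA$values[-i1] - lam)) < tol_simple * mods[i1])
    stop("dominant eigenvalue is not simple (repeated within tolerance); eigenvector derivatives are undefined")
  if (gap > 1 - tol_simple)
    warning("no strict modulus dominance (imprimitive matrix); asymptotic growth is still the Perron root but convergence to the stable structure fails")
  w <- eA$vectors[, i1]
  if (max(abs(Im(w))) > 1e-8 * max(abs(w)))
    stop("dominant right eigenvector is not real")
  w <- Re(w)
  w <- w / sum(w)                      # e'w = 1 (nonnegative for dominant pair)
  eAt <- eigen(t(A))
  j1 <- which.max(Mod(eAt$values))
  v <- Re(eAt$vectors[, j1])
  v <- v / sum(v * w)                  # v'w = 1
  names(w) <- names(v) <- sm$stage_names
  out <- list(lambda = lam, w = w, v = v, gap = gap, A = A, n = n)
  class(out) <- "eigensystem"
  out
}

# reachability check via boolean powers of (I + A)
.is_irreducible <- function(A) {
  n <- nrow(A)
  B <- (A > 0) + diag(n) > 0
  P <- B
  for (k in seq_len(ceiling(log2(max(n - 1, 1))))) P <- (P %*% P) > 0
  all(P)
}

#' @export
print.eigensystem <- function(x, digits = 6, ...) {
  cat(sprintf("Dominant eigensystem: lambda = %.*g (damping ratio |l2|/|l1| = %.3f)\n",
              digits, x$lambda, x$gap))
  cat("w (stable stage distribution, e'w = 1):\n")
  print(round(x$w, digits))
  cat("v (reproductive values, v'w = 1):\n")
  print(round(x$v, digits))
  invisible(x)
}

#' First derivatives of lambda with respect to matrix entries
#'
#' The gradient \eqn{D[\lambda; \mathrm{vec} A]}, a \code{1 x n^2} row
#' vector in vec order.  Under the package's scaling conventions the
#' entry for \eqn{a_{ij}} is the sensitivity \eqn{v_i w_j}.
#'
#' @param es an [dominant_eigensystem()] result, a [stage_matrix()], or a
#'   plain matrix (eigensystem computed on the fly).
#' @return a \code{1 x n^2} matrix with vec-order column labels.
#' @export
dlambda_dvecA <- function(es) {
  es <- as_eigensystem(es)
  D <- matrix(kronecker(es$w, es$v), nrow = 1)   # (w' kron v')
  colnames(D) <- entry_labels(es$n)
  D
}

as_eigensystem <- function(x) {
  if (inherits(x, "eigensystem")) x else dominant_eigensystem(x)
}

# vec-order labels "a[i,j]"
entry_labels <- function(n, sym = "a") {
  idx <- vec_subscripts(seq_len(n * n), n)
  sprintf("%s[%d,%d]", sym, idx[, 1], idx[, 2])
}

# Solve the bordered systems giving the eigenvector Jacobians.
# For dw: (A - lam I) dw - w dlam = -(dA) w, with e' dw = 0.
# For dv: (A' - lam I) dv - v dlam = -(dA)' v, with w' dv = -v' dw
# (differentiated v'w = 1).  Both bordered matrices are nonsingular when
# lambda is simple; a pseudo-inverse fallback covers near-singular cases
# with a warning.
.eig_jacobians <- function(es) {
  A <- es$A; n <- es$n; lam <- es$lambda; w <- es$w; v <- es$v
  if (n == 1) {
    return(list(Jw = matrix(0, 1, 1), Jv = matrix(0, 1, 1)))
  }
  In <- diag(n)
  solve_b <- function(Mb, RHS) {
    tryCatch(solve(Mb, RHS), error = function(e) {
      warning("bordered eigenvector system singular to working precision; using pseudo-inverse")
      MASS::ginv(Mb) %*% RHS
    })
  }
  Mw <- rbind(cbind(A - lam * In, -w), c(rep(1, n), 0))
  RHSw <- rbind(-(t(w) %x% In), matrix(0, 1, n * n))
  Jw <- solve_b(Mw, RHSw)[seq_len(n), , drop = FALSE]
  K <- as.matrix(commutation_matrix(n, n))
  Mv <- rbind(cbind(t(A) - lam * In, -v), c(w, 0))
  RHSv <- rbind(-(t(v) %x% In) %*% K, -t(v) %*% Jw)
  Jv <- solve_b(Mv, RHSv)[seq_len(n), , drop = FALSE]
  list(Jw = Jw, Jv = Jv)
}

#' Jacobians of the scaled eigenvectors
#'
#' Derivatives of the right eigenvector \code{w} (scaled to
#' \eqn{e^T w = 1}) and the left eigenvector \code{v} (scaled to
#' \eqn{v^T w = 1}) with respect to \code{vec(A)}.  They satisfy the
#' differentiated scaling constraints: every column of
#' \code{jacobian_w} sums to zero, and
#' \eqn{v^T (dw) + w^T (dv) = 0} for every perturbation direction.
#'
#' @inheritParams dlambda_dvecA
#' @param M ignored; retained so the Jacobians can be requested directly
#'   from a matrix via \code{jacobian_w(M)}.
#' @return an \code{n x n^2} Jacobian in vec order.
#' @export
jacobian_w <- function(es, M = NULL) {
  es <- as_eigensystem(es)
  J <- .eig_jacobians(es)$Jw
  colnames(J) <- entry_labels(es$n)
  J
}

#' @rdname jacobian_w
#' @export
jacobian_v <- function(es, M = NULL) {
  es <- as_eigensystem(es)
  J <- .eig_jacobians(es)$Jv
  colnames(J) <- entry_labels(es$n)
  J
}
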