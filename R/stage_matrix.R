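#' Stage-structured projection matrix
#'
#' Container for a nonnegative \code{n x n} population projection matrix
#' \code{A}, optionally decomposed as \code{A = U + F} into a transition
#' (survival) matrix \code{U}, whose column sums are survival
#' probabilities and must not exceed 1, and a nonnegative fertility
#' matrix \code{F}.  The decomposition is biological knowledge and must
#' be supplied by the user; it is required for the net reproductive rate
#' and for the survival parameterization.
#'
#' @param A nonnegative square matrix, or \code{NULL} if \code{U} and
#'   \code{F} are given (then \code{A = U + F}).
#' @param U,F optional transition and fertility matrices.
#' @param stage_names optional character vector of stage labels.
#' @param tol tolerance for validation (column sums of \code{U} may
#'   exceed 1 by at most \code{tol}; \code{A - (U + F)} must vanish to
#'   \code{tol}).
#' @return an object of class \code{"stage_matrix"}: a list with
#'   elements \code{A}, \code{U}, \code{F} (the latter two possibly
#'   \code{NULL}), \code{stage_names} and \code{n}.
#' @examples
#' U <- matrix(c(0, 0.5, 0, 0), 2, 2)
#' F <- matrix(c(0, 0, 2, 0), 2, 2)
#' stage_matrix(U = U, F = F)
#' @export
stage_matrix <- function(A = NULL, U = NULL, F = NULL, stage_names = NULL,
                         tol = 1e-8) {
  if (is.null(A) && (is.null(U) || is.null(F)))
    stop("stage_matrix(): supply A, or both U and F")
  if (!is.null(U) && !is.null(F)) {
    U <- as.matrix(U); F <- as.matrix(F)
    if (!identical(dim(U), dim(F)))
      stop("stage_matrix(): U and F must have the same dimensions")
    if (is.null(A)) A <- U + F
  }
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("stage_matrix(): A must be square")
  if (any(!is.finite(A))) stop("stage_matrix(): non-finite entries in A")
  if (any(A < 0)) stop("stage_matrix(): A must be nonnegative")
  if (!is.null(U)) {
    if (any(U < -tol) || any(F < -tol))
      stop("stage_matrix(): U and F must be nonnegative")
    if (max(abs(A - (U + F))) > tol)
      stop("stage_matrix(): A and U + F disagree")
    cs <- colSums(U)
    if (any(cs > 1 + tol))
      stop(sprintf(
        "stage_matrix(): column sums of U exceed 1 (max %.4f); not survival probabilities",
        max(cs)))
  }
  if (is.null(stage_names)) {
    stage_names <- colnames(A)
    if (is.null(stage_names)) stage_names <- paste0("stage", seq_len(n))
  }
  if (length(stage_names) != n)
    stop("stage_matrix(): stage_names must have length n")
  dimnames(A) <- list(stage_names, stage_names)
  if (!is.null(U)) dimnames(U) <- dimnames(F) <- dimnames(A)
  structure(list(A = A, U = U, F = F, stage_names = stage_names, n = n),
            class = "stage_matrix")
}

# accept a stage_matrix or a bare matrix wherever a projection matrix is
# expected
as_stage_matrix <- function(x, ...) {
  if (inherits(x, "stage_matrix")) x else stage_matrix(A = x, ...)
}

#' @export
print.stage_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Stage-structured projection matrix (%d stages)%s\n", x$n,
              if (!is.null(x$U)) ", decomposed A = U + F" else ""))
  print(round(x$A, digits))
  invisible(x)
}
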