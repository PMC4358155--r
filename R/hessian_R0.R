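#' Fundamental matrix of a transient transition matrix
#'
#' \eqn{N = (I - U)^{-1}}; entry \eqn{(i, j)} is the expected number of
#' visits to stage \eqn{i} by an individual starting in stage \eqn{j}.
#' Requires the spectral radius of \code{U} to be below 1 (every
#' individual eventually dies).
#'
#' @param U nonnegative transition matrix with \eqn{\rho(U) < 1}.
#' @return the fundamental matrix \code{N}.
#' @export
fundamental_matrix <- function(U) {
  U <- as.matrix(U)
  n <- nrow(U)
  if (ncol(U) != n) stop("fundamental_matrix(): U must be square")
  rho <- max(Mod(eigen(U, only.values = TRUE)$values))
  if (rho >= 1 - 1e-10)
    stop(sprintf("transition matrix not transient: spectral radius %.6f >= 1", rho))
  solve(diag(n) - U)
}

#' Net reproductive rate and next-generation system
#'
#' Builds the next-generation matrix \eqn{R = F N} with
#' \eqn{N = (I - U)^{-1}} and returns \eqn{R_0}, the dominant eigenvalue
#' of \code{R} (per-generation growth rate).  When only one row of
#' \code{F} is nonzero there is a single type of offspring: \code{R} has
#' a single nonzero row, its only nonzero eigenvalue is the diagonal
#' entry of that row, and \eqn{R_0} is read off as
#' \code{R[offspring_stage, offspring_stage]} without any eigenvector
#' machinery.
#'
#' @param U,F transition and fertility matrices (or a decomposed
#'   [stage_matrix()] as \code{U}, in which case \code{F} is taken from
#'   it).
#' @param offspring_stage index of the offspring stage for the
#'   single-offspring shortcut; by default the nonzero row of \code{F}.
#' @return an object of class \code{"nextgen_system"}: list with
#'   \code{N}, \code{R}, \code{R0}, \code{single_offspring},
#'   \code{offspring_stage}, \code{U}, \code{F}, \code{n}.
#' @examples
#' U <- matrix(c(0, 0.5, 0, 0), 2, 2)
#' F <- matrix(c(0, 0, 2, 0), 2, 2)
#' R0_value(U, F)$R0  # 1
#' @export
R0_value <- function(U, F = NULL, offspring_stage = NULL) {
  if (inherits(U, "stage_matrix")) {
    if (is.null(U$U)) stop("R0_value(): stage matrix has no U/F decomposition")
    F <- U$F; U <- U$U
  }
  U <- as.matrix(U); F <- as.matrix(F)
  if (any(F < 0)) stop("R0_value(): F must be nonnegative")
  n <- nrow(U)
  N <- fundamental_matrix(U)
  R <- F %*% N
  nzrow <- which(rowSums(abs(F)) > 0)
  single <- length(nzrow) <= 1
  if (is.null(offspring_stage))
    offspring_stage <- if (length(nzrow) >= 1) nzrow[1] else 1L
  if (single) {
    R0 <- R[offspring_stage, offspring_stage]
  } else {
    ev <- eigen(R, only.values = TRUE)$values
    i <- which.max(Mod(ev))
    if (abs(Im(ev[i])) > 1e-10 * max(Mod(ev), 1))
      stop("R0_value(): dominant eigenvalue of R is complex")
    R0 <- Re(ev[i])
  }
  structure(list(N = N, R = R, R0 = R0, single_offspring = single,
                 offspring_stage = as.integer(offspring_stage),
                 U = U, F = F, n = n),
            class = "nextgen_system")
}

#' @export
print.nextgen_system <- function(x, digits = 6, ...) {
  cat(sprintf("Next-generation system: R0 = %.*g (%s)\n", digits, x$R0,
              if (x$single_offspring)
                sprintf("single offspring type, stage %d", x$offspring_stage)
              else "multiple offspring types"))
  invisible(x)
}

# gradient and Hessian of R0 as a function of vec(R).  For a single
# offspring type R0 is the (o,o) entry of R: gradient e_o kron e_o,
# Hessian zero.  Otherwise R0 is the dominant eigenvalue of R and the
# lambda machinery applies with R in place of A.
.R0_in_R <- function(ng, method = c("auto", "eigen", "entry")) {
  method <- match.arg(method)
  n <- ng$n
  if (method == "auto") method <- if (ng$single_offspring) "entry" else "eigen"
  if (method == "entry") {
    if (!ng$single_offspring)
      stop("entry method requires a single offspring type")
    o <- ng$offspring_stage
    D <- matrix(0, 1, n * n)
    D[vec_index(o, o, n)] <- 1
    list(D = D, H = matrix(0, n * n, n * n), value = ng$R0)
  } else {
    # R is typically reducible (only offspring rows are nonzero); the
    # reducibility warning is expected and uninformative here
    smR <- stage_matrix(A = ng$R)
    esR <- withCallingHandlers(
      dominant_eigensystem(smR),
      warning = function(w) {
        if (grepl("reducible", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    HR <- hessian_lambda_A(smR, es = esR)
    list(D = HR$D, H = HR$H, value = esR$lambda)
  }
}

#' Hessian of R0 with respect to transition-matrix entries
#'
#' Chain rule through \eqn{\mathrm{vec}R}: since \eqn{dN = N\,dU\,N},
#' the Jacobian is \eqn{D[\mathrm{vec}R; \mathrm{vec}U] = N^T \otimes
#' FN}, and the curvature of the inner map contributes the contraction
#' of \eqn{D[R_0; \mathrm{vec}R]} with the stacked Hessian
#' \eqn{H[\mathrm{vec}R; \mathrm{vec}U]}, whose component form is
#' \deqn{\partial^2 R_{ij} / \partial u_{ab}\,\partial u_{cd}
#'   = (FN)_{ia} N_{bc} N_{dj} + (FN)_{ic} N_{da} N_{bj}.}
#' The contraction is evaluated in closed form (rank-one gradient of an
#' eigenvalue), avoiding the \eqn{n^4 \times n^2} stack.
#'
#' @inheritParams R0_value
#' @param method \code{"entry"} uses the single-offspring shortcut
#'   (\eqn{R_0 = R[o,o]}), \code{"eigen"} the eigenvalue machinery on
#'   \code{R}; \code{"auto"} picks by the structure of \code{F}.
#' @return a [growth_hessian_object()] with \code{rate = "R0"},
#'   \code{wrt = "U"}.
#' @export
hessian_R0_U <- function(U, F = NULL, offspring_stage = NULL,
                         method = c("auto", "eigen", "entry")) {
  ng <- R0_value(U, F, offspring_stage)
  r0 <- .R0_in_R(ng, method)
  n <- ng$n
  N <- ng$N
  FN <- ng$R
  J <- t(N) %x% FN                       # D[vecR; vecU]
  term1 <- t(J) %*% r0$H %*% J
  # contraction sum_ij D_ij H[R_ij; vecU] with D = v w' (or e_o e_o'):
  # alpha_a N_bc beta_d  +  transpose, alpha = (FN)'v, beta = N w
  dW <- unvec(as.numeric(r0$D), n)       # D as matrix over (i,j)
  sv <- svd(dW, nu = 1, nv = 1)          # rank-1: d = s * u v'
  al <- as.numeric(t(FN) %*% (sv$u[, 1] * sv$d[1]))
  be <- as.numeric(N %*% sv$v[, 1])
  arr <- outer(outer(al, N), be)         # (a, b, c, d)
  M1 <- matrix(arr, n * n, n * n)
  B <- term1 + M1 + t(M1)
  Dout <- r0$D %*% J
  growth_hessian_object(B, "R0", "U", entry_labels(n, "u"),
                        value = r0$value, D = Dout, n = n)
}

#' Hessian of R0 with respect to fertility-matrix entries
#'
#' \eqn{R = FN} is linear in \code{F} (the inner-map Hessian is zero), so
#' only the eigenvalue-curvature quadratic form survives:
#' \deqn{H[R_0; \mathrm{vec}F] = (N \otimes I)\, H[R_0; \mathrm{vec}R]\,
#'   (N^T \otimes I).}
#' With a single offspring type \eqn{R_0} is the \eqn{(o,o)} entry of
#' \eqn{FN}, linear in \code{F}, and the Hessian is exactly zero.
#'
#' @inheritParams hessian_R0_U
#' @return a [growth_hessian_object()] with \code{wrt = "F"}.
#' @export
hessian_R0_F <- function(U, F = NULL, offspring_stage = NULL,
                         method = c("auto", "eigen", "entry")) {
  ng <- R0_value(U, F, offspring_stage)
  r0 <- .R0_in_R(ng, method)
  n <- ng$n
  J <- t(ng$N) %x% diag(n)               # D[vecR; vecF]
  B <- t(J) %*% r0$H %*% J
  growth_hessian_object(B, "R0", "F", entry_labels(n, "f"),
                        value = r0$value, D = r0$D %*% J, n = n)
}

#' Hessian of R0 with respect to lower-level parameters
#'
#' General chain rule through \eqn{(U(\theta), F(\theta))}.  With
#' \eqn{dN = N\,dU\,N} the second differential of \eqn{R = FN} along
#' parameter directions \eqn{(p, q)} is
#' \deqn{\partial^2 R/\partial\theta_p \partial\theta_q =
#'   F_{pq} N + F_p N U_q N + F_q N U_p N +
#'   F\,(N U_{pq} N + N U_p N U_q N + N U_q N U_p N),}
#' where subscripts on \code{U} and \code{F} denote the map's first and
#' second parameter derivatives.  The Hessian of the rate is then
#' \eqn{J_R^T H[R_0; \mathrm{vec}R] J_R} plus the contraction of
#' \eqn{D[R_0; \mathrm{vec}R]} with these second differentials.  With a
#' single offspring type the shortcut \eqn{R_0 = e_o^T F N e_o} gives
#' \eqn{H_{pq} = e_o^T (\partial^2 R/\partial\theta_p\partial\theta_q)
#' e_o} with no eigenvector machinery; the two paths agree to machine
#' precision.
#'
#' @inheritParams hessian_R0_U
#' @param map a [parameter_map()] whose build returns a \code{U}/\code{F}
#'   decomposition (e.g. [survival_map()] or a [custom_map()] returning
#'   \code{list(U = , F = )}).
#' @return a [growth_hessian_object()] over the map's parameters.
#' @export
hessian_R0_theta <- function(U = NULL, F = NULL, map,
                             offspring_stage = NULL,
                             method = c("auto", "eigen", "entry")) {
  if (is.null(map$jac_U))
    stop("hessian_R0_theta(): map must carry a U/F decomposition")
  if (!is.null(U)) {
    if (inherits(U, "stage_matrix")) { F <- U$F; U <- U$U }
    if (max(abs(U - map$U)) > 1e-8 || max(abs(F - map$F)) > 1e-8)
      stop("hessian_R0_theta(): supplied U/F disagree with the map's evaluation point")
  }
  ng <- R0_value(map$U, map$F, offspring_stage)
  r0 <- .R0_in_R(ng, method)
  n <- ng$n; s <- map$s
  N <- ng$N; Fm <- ng$F
  Up <- lapply(seq_len(s), function(p) unvec(map$jac_U[, p], n))
  Fp <- lapply(seq_len(s), function(p) unvec(map$jac_F[, p], n))
  # Jacobian of vecR in theta
  JR <- vapply(seq_len(s), function(p)
    vec(Fp[[p]] %*% N + Fm %*% N %*% Up[[p]] %*% N), numeric(n * n))
  JR <- matrix(JR, nrow = n * n)
  Dvec <- as.numeric(r0$D)
  B <- t(JR) %*% r0$H %*% JR
  hU <- map$hess_U; hF <- map$hess_F
  second <- function(p, q) {
    # stacked layout: row block k = Hessian of component k; entry (p, q)
    # of block k is hess[(k-1)*s + p, q]
    Upq <- unvec(hU[(seq_len(n * n) - 1L) * s + p, q], n)
    Fpq <- unvec(hF[(seq_len(n * n) - 1L) * s + p, q], n)
    NUp <- N %*% Up[[p]] %*% N
    NUq <- N %*% Up[[q]] %*% N
    Fpq %*% N + Fp[[p]] %*% NUq + Fp[[q]] %*% NUp +
      Fm %*% (N %*% Upq %*% N + NUp %*% Up[[q]] %*% N + NUq %*% Up[[p]] %*% N)
  }
  for (p in seq_len(s)) for (q in seq_len(p)) {
    d2 <- sum(Dvec * vec(second(p, q)))
    B[p, q] <- B[p, q] + d2
    if (q < p) B[q, p] <- B[q, p] + d2
  }
  growth_hessian_object(B, "R0", "theta", map$names,
                        value = r0$value, D = matrix(Dvec, 1) %*% JR, n = n)
}
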