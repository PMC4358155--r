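#' Hessian of the invasion exponent r = log(lambda)
#'
#' Differentiating \eqn{D[r] = D[\lambda] / \lambda} once more gives the
#' closed transform
#' \deqn{H[r; \mathrm{vec}A] = \frac{1}{\lambda} H[\lambda; \mathrm{vec}A]
#'  - \frac{1}{\lambda^2} D^T D,}
#' with \eqn{D = D[\lambda; \mathrm{vec}A]}.  The hard part (the
#' eigenvalue Hessian) is computed once by [hessian_lambda_A()]; the
#' log transform is cheap and shares that single code path.
#'
#' @inheritParams hessian_lambda_A
#' @return a [growth_hessian_object()] with \code{rate = "r"}.
#' @export
hessian_r_A <- function(M, es = NULL) {
  sm <- as_stage_matrix(M)
  if (is.null(es)) es <- dominant_eigensystem(sm)
  if (es$lambda <= 0) stop("hessian_r_A(): lambda <= 0, log undefined")
  HL <- hessian_lambda_A(sm, es = es)
  .log_transform(HL, rate = "r")
}

# H[log f] = H[f]/f - D'D/f^2, applied to any growth_hessian of lambda
# or of lambda-like positive rates
.log_transform <- function(Hf, rate = "r") {
  lam <- Hf$value
  D <- Hf$D
  H <- Hf$H / lam - crossprod(D) / lam^2
  out <- growth_hessian_object(H, rate, Hf$wrt, Hf$variables,
                               value = log(lam), D = D / lam, n = Hf$n)
  out
}

#' Hessian of r with respect to lower-level parameters
#'
#' Applies the same log transform to \eqn{H[\lambda; \theta]} and
#' \eqn{D[\lambda; \theta]}:
#' \eqn{H[r; \theta] = H[\lambda; \theta]/\lambda - D_\theta^T
#' D_\theta/\lambda^2}.  Equals [hessian_r_A()] under the identity map.
#'
#' @inheritParams hessian_lambda_theta
#' @return a [growth_hessian_object()].
#' @export
hessian_r_theta <- function(M = NULL, map) {
  HL <- hessian_lambda_theta(M, map)
  if (HL$value <= 0) stop("hessian_r_theta(): lambda <= 0, log undefined")
  .log_transform(HL, rate = "r")
}
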