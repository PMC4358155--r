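#' Labelled Hessian of a population growth rate
#'
#' The common return class of all second-derivative computations.  The
#' Hessian is symmetrized as \code{(H + t(H)) / 2} after asserting
#' near-symmetry of the raw analytic result; floating-point asymmetry
#' would otherwise pollute downstream quadratic forms.
#'
#' @param H square numeric matrix of second derivatives.
#' @param rate one of \code{"lambda"}, \code{"r"}, \code{"R0"}.
#' @param wrt what the derivatives are taken with respect to
#'   (\code{"A"}, \code{"U"}, \code{"F"}, \code{"sigma"}, \code{"theta"},
#'   ...).
#' @param variables ordered variable labels (vec-indexed entry pairs such
#'   as \code{"a[3,1]"}, or parameter names).
#' @param value the value of the growth rate at the evaluation point.
#' @param D the gradient (first derivatives) at the evaluation point, as
#'   a \code{1 x s} matrix.
#' @param n stage count of the underlying projection matrix.
#' @return an object of class \code{"growth_hessian"}.
#' @export
growth_hessian_object <- function(H, rate, wrt, variables, value = NA_real_,
                                  D = NULL, n = NA_integer_) {
  H <- as.matrix(H)
  s <- nrow(H)
  if (ncol(H) != s) stop("growth_hessian_object(): H must be square")
  if (length(variables) != s)
    stop("growth_hessian_object(): variable labels do not match H dimensions")
  H <- .symmetrize(H, label = sprintf("H[%s; %s]", rate, wrt))
  asym <- attr(H, "asym"); attr(H, "asym") <- NULL
  dimnames(H) <- list(variables, variables)
  if (!is.null(D)) {
    D <- matrix(as.numeric(D), nrow = 1)
    colnames(D) <- variables
  }
  structure(list(H = H, rate = rate, wrt = wrt, variables = variables,
                 value = value, D = D, n = n, symmetrized = TRUE,
                 asym = asym),
            class = "growth_hessian")
}

#' @export
print.growth_hessian <- function(x, digits = 4, max_show = 8, ...) {
  s <- length(x$variables)
  cat(sprintf("Hessian of %s with respect to %s: %d x %d symmetric matrix\n",
              x$rate, x$wrt, s, s))
  if (!is.na(x$value))
    cat(sprintf("  %s at evaluation point: %.6g\n", x$rate, x$value))
  k <- min(s, max_show)
  print(round(x$H[seq_len(k), seq_len(k), drop = FALSE], digits))
  if (s > k) cat(sprintf("  ... (%d more rows/columns)\n", s - k))
  invisible(x)
}

#' @export
summary.growth_hessian <- function(object, top = 5, ...) {
  H <- object$H
  s <- nrow(H)
  d <- diag(H)
  ut <- upper.tri(H, diag = TRUE)
  ord <- order(abs(H[ut]), decreasing = TRUE)
  idx <- which(ut, arr.ind = TRUE)[ord[seq_len(min(top, sum(ut)))], ,
                                   drop = FALSE]
  largest <- data.frame(
    row = object$variables[idx[, 1]],
    col = object$variables[idx[, 2]],
    value = H[idx])
  out <- list(rate = object$rate, wrt = object$wrt, dim = s,
              value = object$value, asym = object$asym,
              range_diag = range(d), largest = largest)
  class(out) <- "summary.growth_hessian"
  out
}

#' @export
print.summary.growth_hessian <- function(x, ...) {
  cat(sprintf("H[%s; %s]: %d x %d, relative asymmetry before symmetrization %.2g\n",
              x$rate, x$wrt, x$dim, x$dim, x$asym))
  cat(sprintf("diagonal (pure second derivatives) in [%.4g, %.4g]\n",
              x$range_diag[1], x$range_diag[2]))
  cat("largest-magnitude entries:\n")
  print(x$largest, row.names = FALSE)
  invisible(x)
}

#' @export
as.matrix.growth_hessian <- function(x, ...) x$H

#' Long-format view of a Hessian
#'
#' For matrix-entry Hessians the columns are
#' \code{(row_i, row_j, col_i, col_j, value)} where \code{(row_i, row_j)}
#' are the 1-based subscripts of the vec-indexed row variable; for
#' parameter Hessians the columns are
#' \code{(param_row, param_col, value)}.
#'
#' @param x a \code{growth_hessian}.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.growth_hessian <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  s <- nrow(x$H)
  entrywise <- x$wrt %in% c("A", "U", "F", "R") && s == x$n^2
  rows <- rep(seq_len(s), times = s)
  cols <- rep(seq_len(s), each = s)
  if (entrywise) {
    ri <- vec_subscripts(rows, x$n)
    ci <- vec_subscripts(cols, x$n)
    data.frame(row_i = ri[, 1], row_j = ri[, 2],
               col_i = ci[, 1], col_j = ci[, 2],
               value = as.numeric(x$H))
  } else {
    data.frame(param_row = x$variables[rows],
               param_col = x$variables[cols],
               value = as.numeric(x$H))
  }
}

#' Heatmap of a Hessian matrix
#'
#' Simple diagnostic image of the second-derivative matrix, with a
#' symmetric diverging palette centred at zero.  Entries corresponding
#' to structural zeros of the projection matrix can be masked.
#'
#' @param x a \code{growth_hessian}.
#' @param mask optional logical vector over the variables (TRUE = show);
#'   for matrix-entry Hessians, [nonzero_mask()] gives the observed
#'   transitions.
#' @param ... passed to [graphics::image()].
#' @export
plot.growth_hessian <- function(x, mask = NULL, ...) {
  H <- x$H
  if (!is.null(mask)) H <- H[mask, mask, drop = FALSE]
  s <- nrow(H)
  lim <- max(abs(H))
  pal <- grDevices::hcl.colors(65, "Blue-Red 3")
  graphics::image(seq_len(s), seq_len(s), t(H[rev(seq_len(s)), , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, xlab = "", ylab = "",
                  axes = FALSE,
                  main = sprintf("H[%s; %s]", x$rate, x$wrt), ...)
  invisible(x)
}

#' Mask of observed (nonzero) projection-matrix entries
#'
#' Reports over all \code{n^2} entry pairs can exclude transitions fixed
#' at zero; this returns the vec-order logical mask of entries observed
#' nonzero in \code{A}.
#'
#' @param M a [stage_matrix()] or plain matrix.
#' @return logical vector of length \code{n^2} in vec order.
#' @export
nonzero_mask <- function(M) {
  as.vector(as_stage_matrix(M)$A != 0)
}

#' Hessians of population growth rates
#'
#' Umbrella interface: computes the Hessian of the chosen growth rate
#' (\code{lambda}, \code{r = log lambda}, or \code{R0}) with respect to
#' the chosen variables, dispatching to the specific routines
#' ([hessian_lambda_A()], [hessian_lambda_theta()], [hessian_r_A()],
#' [hessian_r_theta()], [hessian_R0_U()], [hessian_R0_F()],
#' [hessian_R0_theta()]).
#'
#' @param M a [stage_matrix()] (decomposed into \code{U} and \code{F}
#'   when \code{rate = "R0"} or \code{wrt = "sigma"}) or plain matrix.
#' @param rate growth rate to differentiate.
#' @param wrt \code{"A"}, \code{"U"}, \code{"F"}, \code{"sigma"} (the
#'   built-in survival parameterization) or \code{"theta"} (requires
#'   \code{map}).
#' @param map a [parameter_map()] when \code{wrt = "theta"}.
#' @param ... passed to the specific routines.
#' @return a \code{growth_hessian} object.
#' @examples
#' A <- matrix(c(0, 0.5, 2, 0), 2, 2)
#' growth_hessian(A, rate = "r", wrt = "A")
#' @export
growth_hessian <- function(M, rate = c("lambda", "r", "R0"),
                           wrt = c("A", "U", "F", "sigma", "theta"),
                           map = NULL, ...) {
  rate <- match.arg(rate)
  wrt <- match.arg(wrt)
  sm <- as_stage_matrix(M)
  if (wrt == "sigma") map <- survival_map(sm)
  if (wrt %in% c("sigma", "theta") && is.null(map))
    stop("growth_hessian(): wrt = 'theta' requires a parameter map")
  out <- switch(paste(rate, wrt),
    "lambda A" = hessian_lambda_A(sm, ...),
    "lambda sigma" = ,
    "lambda theta" = hessian_lambda_theta(sm, map, ...),
    "r A" = hessian_r_A(sm, ...),
    "r sigma" = ,
    "r theta" = hessian_r_theta(sm, map, ...),
    "R0 U" = hessian_R0_U(sm$U, sm$F, ...),
    "R0 F" = hessian_R0_F(sm$U, sm$F, ...),
    "R0 sigma" = ,
    "R0 theta" = hessian_R0_theta(sm$U, sm$F, map = map, ...),
    stop(sprintf("growth_hessian(): rate '%s' with wrt '%s' is not available",
                 rate, wrt))
  )
  if (wrt == "sigma") out$wrt <- "sigma"
  out
}
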