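#' Classify nonlinear and correlational selection from a Hessian
#'
#' When the growth rate is read as fitness, its pure (diagonal) second
#' derivatives are quadratic selection gradients: negative, near-zero
#' and positive values correspond to concave, linear and convex
#' selection on the trait.  Mixed (off-diagonal) second derivatives
#' measure correlational selection: a negative value is selection to
#' decrease the phenotypic correlation between the two traits, a
#' positive value selection to increase it.
#'
#' The "zero" band is a tolerance choice: by default 5% of the largest
#' absolute diagonal entry, which is explicit and overridable.
#'
#' @param H a [growth_hessian_object()] or plain symmetric matrix.
#' @param tol half-width of the band treated as zero; default
#'   \code{0.05 * max(abs(diag(H)))}.
#' @return an object of class \code{"selection_report"}: list with
#'   \code{traits} (data frame: trait, d2, class), \code{pairs} (data
#'   frame over unordered pairs: trait_i, trait_j, d2, sign), \code{tol}
#'   and \code{rate}.
#' @export
classify_selection <- function(H, tol = NULL) {
  rate <- if (inherits(H, "growth_hessian")) H$rate else NA_character_
  vars <- if (inherits(H, "growth_hessian")) H$variables else NULL
  Hm <- if (inherits(H, "growth_hessian")) H$H else as.matrix(H)
  s <- nrow(Hm)
  if (is.null(vars)) vars <- rownames(Hm)
  if (is.null(vars)) vars <- paste0("trait", seq_len(s))
  if (max(abs(Hm - t(Hm))) > 1e-8 * max(abs(Hm), 1))
    stop("classify_selection(): H must be symmetric")
  d <- diag(Hm)
  if (is.null(tol)) tol <- 0.05 * max(abs(d))
  cls <- ifelse(abs(d) <= tol, "linear", ifelse(d < 0, "concave", "convex"))
  traits <- data.frame(trait = vars, d2 = unname(d), class = cls,
                       stringsAsFactors = FALSE)
  if (s > 1) {
    ij <- which(upper.tri(Hm), arr.ind = TRUE)
    val <- Hm[ij]
    sgn <- ifelse(abs(val) <= tol, "none",
                  ifelse(val < 0, "negative", "positive"))
    pairs <- data.frame(trait_i = vars[ij[, 1]], trait_j = vars[ij[, 2]],
                        d2 = val, sign = sgn, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(trait_i = character(0), trait_j = character(0),
                        d2 = numeric(0), sign = character(0))
  }
  structure(list(traits = traits, pairs = pairs, tol = tol, rate = rate),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection classification (rate: %s, zero band: +/- %.4g)\n",
              x$rate, x$tol))
  cat("per-trait (quadratic selection gradients):\n")
  print(x$traits, row.names = FALSE)
  if (nrow(x$pairs) > 0 && nrow(x$pairs) <= 40) {
    cat("pairwise (correlational selection):\n")
    print(x$pairs, row.names = FALSE)
  } else if (nrow(x$pairs) > 0) {
    tab <- table(x$pairs$sign)
    cat(sprintf("pairwise: %d pairs (%s)\n", nrow(x$pairs),
                paste(names(tab), tab, sep = ": ", collapse = ", ")))
  }
  invisible(x)
}

#' Evolutionary stability of a singular strategy
#'
#' At a singular strategy (zero selection gradient), the sign of the
#' pure second derivative of invasion fitness with respect to the mutant
#' trait decides stability: negative means an evolutionarily stable
#' strategy (an unbeatable endpoint), positive an evolutionarily
#' unstable strategy (a potential branching point).
#'
#' @param d2 pure second derivative(s) of invasion fitness in the mutant
#'   trait at the singular strategy (vectorised).
#' @param tol band treated as degenerate.
#' @return character vector in \code{{"stable", "unstable",
#'   "degenerate"}}.
#' @export
ess_stability <- function(d2, tol = 1e-8) {
  ifelse(d2 < -tol, "stable", ifelse(d2 > tol, "unstable", "degenerate"))
}

#' Selection gradient root helper
#'
#' Thin convenience wrapper locating a zero of a one-parameter selection
#' gradient \eqn{d\lambda/d\theta} by root finding; provided for
#' locating candidate singular strategies, not a second-derivative
#' method.
#'
#' @param build function mapping a scalar trait value to a projection
#'   matrix.
#' @param interval search interval for [stats::uniroot()].
#' @param ... passed to [stats::uniroot()].
#' @return the [stats::uniroot()] result.
#' @export
selection_gradient_root <- function(build, interval, ...) {
  grad <- function(y) {
    m <- suppressMessages(custom_map(function(th) build(th[1]), theta = y))
    es <- dominant_eigensystem(m$A)
    as.numeric(dlambda_dvecA(es) %*% m$jac_A)
  }
  stats::uniroot(grad, interval, ...)
}
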