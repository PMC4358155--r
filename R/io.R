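#' Read a projection matrix from a delimited text file
#'
#' Comma-delimited by default, with whitespace tolerated; lines starting
#' with \code{#} are comments.  An optional first non-comment row of
#' non-numeric fields is taken as stage labels.  Parse problems (ragged
#' rows, non-numeric or negative entries, dimension mismatches) raise
#' errors citing the offending line.
#'
#' @param path file for the full matrix \code{A}; alternatively supply
#'   \code{U_path} and \code{F_path} for a decomposed model.
#' @param U_path,F_path optional paths to the transition and fertility
#'   matrices.
#' @return a [stage_matrix()].
#' @export
read_model <- function(path = NULL, U_path = NULL, F_path = NULL) {
  if (!is.null(U_path) || !is.null(F_path)) {
    if (is.null(U_path) || is.null(F_path))
      stop("read_model(): supply both U_path and F_path")
    U <- .read_matrix_file(U_path)
    F <- .read_matrix_file(F_path)
    if (!identical(dim(U$M), dim(F$M)))
      stop(sprintf("read_model(): U (%s) and F (%s) dimensions differ",
                   U_path, F_path))
    return(stage_matrix(U = U$M, F = F$M,
                        stage_names = U$labels %||% F$labels))
  }
  if (is.null(path)) stop("read_model(): no input file given")
  A <- .read_matrix_file(path)
  stage_matrix(A = A$M, stage_names = A$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_matrix_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0) stop(sprintf("%s: no data lines", path))
  split1 <- function(line) {
    line <- gsub("^\\s+|\\s+$", "", line)
    strsplit(line, "\\s*,\\s*|\\s+")[[1]]
  }
  fields <- lapply(raw[keep], split1)
  labels <- NULL
  first <- suppressWarnings(as.numeric(fields[[1]]))
  if (any(is.na(first))) {
    labels <- fields[[1]]
    fields <- fields[-1]
    keep <- keep[-1]
  }
  if (length(fields) == 0) stop(sprintf("%s: header but no data rows", path))
  ncols <- length(fields[[1]])
  rows <- vector("list", length(fields))
  for (r in seq_along(fields)) {
    if (length(fields[[r]]) != ncols)
      stop(sprintf("%s: line %d has %d fields, expected %d (ragged row)",
                   path, keep[r], length(fields[[r]]), ncols))
    x <- suppressWarnings(as.numeric(fields[[r]]))
    if (any(is.na(x)))
      stop(sprintf("%s: line %d contains non-numeric entries", path, keep[r]))
    if (any(x < 0))
      stop(sprintf("%s: line %d contains negative entries", path, keep[r]))
    rows[[r]] <- x
  }
  M <- do.call(rbind, rows)
  list(M = M, labels = labels)
}

#' Write a matrix as delimited text
#'
#' Full-precision export (17 significant digits) so that write/read
#' round trips are bit-identical.
#'
#' @param M matrix (or [stage_matrix()], whose \code{A} is written).
#' @param path output file.
#' @param labels write stage labels as a header row.
#' @export
write_matrix <- function(M, path, labels = TRUE) {
  sm <- if (inherits(M, "stage_matrix")) M else NULL
  A <- if (is.null(sm)) as.matrix(M) else sm$A
  con <- file(path, "w")
  on.exit(close(con))
  if (labels && !is.null(colnames(A)))
    writeLines(paste(colnames(A), collapse = ","), con)
  apply(A, 1, function(r)
    writeLines(paste(sprintf("%.17g", r), collapse = ","), con))
  invisible(path)
}

#' Export and import Hessian matrices
#'
#' Three formats: \code{"square"} (the matrix with variable labels, plus
#' \code{# rate:}/\code{# wrt:} metadata comments), \code{"long"} (one
#' row per entry pair: columns \code{row_i, row_j, col_i, col_j, value}
#' for matrix-entry Hessians, \code{param_row, param_col, value} for
#' parameter Hessians) and \code{"json"}.  Values are written with 10
#' significant digits.
#'
#' @param H a [growth_hessian_object()].
#' @param path output file.
#' @param format export format.
#' @export
write_hessian <- function(H, path, format = c("square", "long", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(H, "growth_hessian"))
  if (format == "json") {
    jsonlite::write_json(
      list(rate = H$rate, wrt = H$wrt, n = H$n, value = H$value,
           variables = H$variables, H = H$H),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate: %s", H$rate), sprintf("# wrt: %s", H$wrt),
               sprintf("# n: %d", H$n), sprintf("# value: %.10g", H$value)),
             con)
  if (format == "square") {
    # labels such as "a[1,1]" contain commas: quote all fields
    df <- data.frame(variable = H$variables,
                     matrix(sprintf("%.10g", H$H), nrow(H$H)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[-1] <- H$variables
    utils::write.table(df, con, sep = ",", quote = TRUE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    df <- as.data.frame(H)
    writeLines(paste(names(df), collapse = ","), con)
    val <- sprintf("%.10g", df$value)
    left <- df[setdiff(names(df), "value")]
    writeLines(do.call(paste, c(left, list(val), sep = ",")), con)
  }
  invisible(path)
}

#' @rdname write_hessian
#' @export
read_hessian <- function(path, format = c("square", "long", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(growth_hessian_object(x$H, x$rate, x$wrt,
                                 as.character(x$variables),
                                 value = x$value, n = as.integer(x$n)))
  }
  raw <- readLines(path, warn = FALSE)
  meta <- function(key, cast = identity) {
    ln <- grep(sprintf("^# %s:", key), raw, value = TRUE)
    if (length(ln) == 0) return(NULL)
    cast(sub(sprintf("^# %s:\\s*", key), "", ln[1]))
  }
  rate <- meta("rate") %||% "lambda"
  wrt <- meta("wrt") %||% "A"
  n <- meta("n", as.integer) %||% NA_integer_
  value <- meta("value", as.numeric) %||% NA_real_
  body <- raw[!grepl("^\\s*(#|$)", raw)]
  if (format == "square") {
    df <- utils::read.csv(textConnection(body), check.names = FALSE,
                          stringsAsFactors = FALSE)
    vars <- as.character(df[[1]])
    H <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(H) <- "double"
    growth_hessian_object(H, rate, wrt, vars, value = value, n = n)
  } else {
    df <- utils::read.csv(textConnection(body), comment.char = "#")
    if (all(c("row_i", "row_j") %in% names(df))) {
      s <- n * n
      H <- matrix(NA_real_, s, s)
      H[cbind(vec_index(df$row_i, df$row_j, n),
              vec_index(df$col_i, df$col_j, n))] <- df$value
      vars <- entry_labels(n, substr(wrt, 1, 1))
      if (wrt == "A") vars <- entry_labels(n, "a")
    } else {
      vars <- unique(df$param_row)
      s <- length(vars)
      H <- matrix(NA_real_, s, s, dimnames = list(vars, vars))
      H[cbind(match(df$param_row, vars), match(df$param_col, vars))] <- df$value
    }
    growth_hessian_object(H, rate, wrt, vars, value = value, n = n)
  }
}

#' Random Lefkovitch (stage-classified) matrix generator
#'
#' Generates a reproducible random stage-structured model: a random
#' column-stochastic conditional-transition matrix \code{G} biased
#' toward stasis and single-stage growth (with shrinkage), survival
#' probabilities \eqn{\sigma_j \in (0.05, 0.95)}, so the transition
#' matrix \code{U = G diag(sigma)} has column sums \eqn{\sigma_j < 1},
#' and lognormal fertilities from the designated fraction of the oldest
#' stages into stage 1.  A small positive loop is added when needed to
#' guarantee irreducibility.
#'
#' Draws are rejected (and redrawn from the same seeded stream) unless
#' the net reproductive rate lies in \eqn{[0.1, 10]}: unconstrained
#' chains of low survivals can produce life cycles in which offspring
#' essentially never recruit (per-generation replacement of
#' \eqn{10^{-3}} or less), which no persisting population exhibits and
#' whose growth-rate curvatures are too ill-conditioned to be
#' meaningful.
#'
#' @param n number of stages (>= 2).
#' @param seed optional integer seed (RNG state restored on exit).
#' @param frac_fertile fraction of stages (the oldest ones) that
#'   reproduce.
#' @param offspring_stages stage(s) receiving the offspring (rows of
#'   \code{F}); more than one gives a multiple-offspring-type model.
#' @return a [stage_matrix()] with \code{U}/\code{F} decomposition.
#' @export
random_lefkovitch <- function(n, seed = NULL, frac_fertile = 0.5,
                              offspring_stages = 1L) {
  if (n < 2) stop("random_lefkovitch(): n must be >= 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  for (attempt in 1:50) {
    G <- matrix(0, n, n)
    for (j in seq_len(n)) {
      targets <- c(stay = j, grow = if (j < n) j + 1L else NA,
                   shrink = if (j > 1) j - 1L else NA)
      wts <- c(stats::rgamma(1, 3), if (j < n) stats::rgamma(1, 3),
               if (j > 1) stats::rgamma(1, 1))
      targets <- targets[!is.na(targets)]
      G[targets, j] <- wts / sum(wts)
    }
    sigma <- stats::runif(n, 0.05, 0.95)
    U <- G %*% diag(sigma)
    F <- matrix(0, n, n)
    nf <- max(1L, ceiling(frac_fertile * n))
    fert <- (n - nf + 1L):n
    for (o in offspring_stages)
      F[o, fert] <- stats::rlnorm(nf, meanlog = 0.3, sdlog = 0.5)
    A <- U + F
    if (!.is_irreducible(A)) {
      F[offspring_stages[1], n] <- F[offspring_stages[1], n] + 1e-3
    }
    r0 <- tryCatch(R0_value(U, F)$R0, error = function(e) NA_real_)
    if (is.finite(r0) && r0 >= 0.1 && r0 <= 10)
      return(stage_matrix(U = U, F = F))
  }
  stop("random_lefkovitch(): no demographically plausible draw in 50 attempts")
}

#' Synthetic Calathea-style demonstration model
#'
#' An 8-stage stage-classified model for a *Calathea ovandensis*-type
#' understory herb (seed, seedling, juvenile, pre-reproductive, and
#' four reproductive size classes), shipped as plain-text \code{U} and
#' \code{F} fixtures.  This matrix is a synthetic stand-in constructed
#' from plausible vital rates for demonstration and testing; it is
#' \emph{not} the published field-estimated matrix for the species,
#' whose weighted-mean projection matrix has dominant eigenvalue
#' 0.9923.  Use [calathea_matrix()] with \code{path} to load and
#' checksum-validate a transcription of the published matrix.
#'
#' @return a [stage_matrix()] with \code{U}/\code{F} decomposition and
#'   stage labels.
#' @export
synthetic_calathea <- function() {
  read_model(
    U_path = system.file("extdata", "synthetic_calathea_U.csv",
                         package = "demhess", mustWork = TRUE),
    F_path = system.file("extdata", "synthetic_calathea_F.csv",
                         package = "demhess", mustWork = TRUE))
}

#' Case-study matrix loader with eigenvalue checksum
#'
#' Loads an 8-stage *Calathea ovandensis* projection matrix.  When
#' \code{path} is given it must point to a transcription of the
#' published weighted-mean matrix (full \code{A}; fertilities are taken
#' as the stage-1-row contributions of the reproductive stages 5-8 and
#' everything else as transitions); the transcription is validated
#' against the published dominant eigenvalue 0.9923 and loading fails
#' loudly if the eigenvalue differs by more than \code{tol}.  Without a
#' \code{path} the packaged [synthetic_calathea()] stand-in is returned
#' (with a message; the checksum does not apply to the synthetic
#' matrix).
#'
#' @param path optional file with the transcribed published matrix.
#' @param check validate the eigenvalue checksum (ignored for the
#'   synthetic stand-in).
#' @param tol checksum tolerance on the dominant eigenvalue.
#' @return a [stage_matrix()].
#' @export
calathea_matrix <- function(path = NULL, check = TRUE, tol = 5e-4) {
  if (is.null(path)) {
    message("calathea_matrix(): returning the packaged synthetic stand-in; ",
            "supply `path` to load a transcription of the published matrix")
    return(synthetic_calathea())
  }
  sm0 <- read_model(path)
  A <- sm0$A
  if (nrow(A) != 8) stop("calathea_matrix(): expected an 8-stage matrix")
  F <- matrix(0, 8, 8)
  F[1, 5:8] <- A[1, 5:8]
  sm <- stage_matrix(A = A, U = A - F, F = F, stage_names = sm0$stage_names)
  if (check) {
    lam <- dominant_eigensystem(sm)$lambda
    if (abs(lam - 0.9923) > tol)
      stop(sprintf(paste0(
        "calathea_matrix(): transcription checksum failed: dominant ",
        "eigenvalue %.6f differs from the published 0.9923 by more than %g"),
        lam, tol))
  }
  sm
}
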