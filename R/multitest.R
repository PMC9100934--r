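#' Effective number of independent tests (Galwey estimator)
#'
#' Estimates how many approximately independent tests a block of correlated
#' variables represents, from the eigenvalues of their correlation matrix:
#' negative eigenvalues are clipped to zero and
#' \eqn{M_{eff} = \lfloor (\sum_i \sqrt{\lambda_i})^2 / \sum_i \lambda_i \rfloor}.
#' For mutually independent variables this returns the number of variables;
#' for perfectly collinear variables it returns 1.
#'
#' @param x numeric matrix, observations in rows and variables in columns.
#' @param block optional label describing the variable block (e.g. "glycome").
#' @return an object of class `eff_tests`: a list with `block`, `m_eff`
#'   (positive integer) and `eigenvalues` (as used, after clipping).
#' @examples
#' set.seed(1)
#' effective_tests_galwey(matrix(rnorm(300), 100, 3))$m_eff  # 3
#' @export
effective_tests_galwey <- function(x, block = "block") {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (nrow(x) < 3L) stop("need at least 3 observations")
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    bad <- colnames(x)[!is.finite(sds) | sds == 0]
    if (is.null(bad)) bad <- which(!is.finite(sds) | sds == 0)
    stop("constant or degenerate variable(s): ", paste(bad, collapse = ", "))
  }
  cm <- stats::cor(x, use = "pairwise.complete.obs")
  lam <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  m_eff <- as.integer(floor(sum(sqrt(lam))^2 / sum(lam)))
  structure(list(block = block, m_eff = m_eff, eigenvalues = lam),
            class = "eff_tests")
}

#' @export
print.eff_tests <- function(x, ...) {
  cat("Effective tests [", x$block, "]: ", x$m_eff,
      " (", length(x$eigenvalues), " variables)\n", sep = "")
  invisible(x)
}

#' Sidak correction for multiple testing
#'
#' Corrected p = 1 - (1 - p)^M, computed via `log1p`/`expm1` so that tiny
#' nominal p-values do not underflow, and capped at 1. Always bounded above
#' by the Bonferroni correction min(1, M p).
#'
#' @param p numeric vector of nominal p-values in \[0, 1\].
#' @param m number of (effective) independent tests, >= 1. May be an
#'   `eff_tests` object.
#' @return corrected p-values, same length as `p`.
#' @examples
#' sidak_correct(4.24e-08, 2088)  # ~8.85e-05
#' @export
sidak_correct <- function(p, m) {
  if (inherits(m, "eff_tests")) m <- m$m_eff
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, -expm1(m * log1p(-p)))
}

#' Combine effective-test counts across blocks
#'
#' The effective number of tests for a scan over the cartesian product of two
#' (or more) variable blocks is the product of the per-block counts.
#'
#' @param ... `eff_tests` objects or plain counts; alternatively a single list
#'   of them.
#' @param block label for the combined block.
#' @return an `eff_tests` object with `m_eff` equal to the product.
#' @examples
#' combine_effective(24, 87)$m_eff  # 2088
#' @export
combine_effective <- function(..., block = "product") {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "eff_tests"))
    xs <- xs[[1]]
  if (!length(xs)) stop("no blocks supplied")
  ms <- vapply(xs, function(b) if (inherits(b, "eff_tests")) b$m_eff else as.numeric(b), 0)
  stopifnot(all(ms >= 1))
  structure(list(block = block, m_eff = as.integer(round(prod(ms))),
                 eigenvalues = NULL),
            class = "eff_tests")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust]).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
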