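#' Rank-based inverse-normal (quantile) normalization
#'
#' Maps a numeric vector onto normal quantiles through its ranks, using the
#' plotting positions (r - a) / (n + 1 - 2a) with a = 3/8 for n <= 10 and
#' a = 1/2 otherwise (the `ppoints`/`qqnorm` convention). Ties share the
#' average rank and therefore receive equal transformed values.
#'
#' @param x numeric vector, length >= 3, not all equal.
#' @return numeric vector of normal scores, mean ~0, monotone in rank.
#' @export
quantile_normalize <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x[!is.na(x)])) < 2L) stop("no variation in input")
  a <- if (n <= 10L) 3 / 8 else 0.5
  r <- rank(x, ties.method = "average", na.last = "keep")
  stats::qnorm((r - a) / (n + 1 - 2 * a))
}

## Internal OLS engine (QR-based). Returns estimate/se/t/p for the column
## named `term` of the design. Errors on rank deficiency, naming the
## aliased columns, and on n <= p.
ols_term <- function(y, X, term) {
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("n (", n, ") <= number of parameters (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("collinear design; aliased column(s): ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  j <- match(term, colnames(X))
  if (is.na(j)) stop("term not in design: ", term)
  tval <- beta[j] / se[j]
  list(beta = unname(beta[j]), se = unname(se[j]), t = unname(tval),
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), n = n, df = df)
}

## Build a covariate design matrix (intercept + age, sex, bmi, smoking [+ PCs]).
covariate_design <- function(n, covariates = NULL, micro_pcs = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    num <- intersect(c("age", "sex", "bmi", "smoking"), names(cv))
    if (length(num)) {
      if (nrow(cv) != n) stop("covariates do not align with observations")
      X <- cbind(X, as.matrix(data.matrix(cv[num])))
    }
  }
  if (!is.null(micro_pcs)) {
    mp <- as.matrix(micro_pcs)
    if (nrow(mp) != n) stop("micro_pcs do not align with observations")
    colnames(mp) <- paste0("PC", seq_len(ncol(mp)))
    X <- cbind(X, mp)
  }
  X
}

#' Covariate-adjusted taxon-trait association
#'
#' Ordinary least-squares regression of one glycan trait (response) on one
#' quantile-normalized taxon abundance (predictor), adjusting for age, sex,
#' BMI and smoking status, and optionally for microbial principal-component
#' scores. Reports the taxon term.
#'
#' @param taxon_abund numeric vector, one value per individual, already
#'   quantile-normalized (see [quantile_normalize]).
#' @param trait numeric vector, analysis-ready trait values.
#' @param covariates data.frame with columns among age, sex, bmi, smoking
#'   (sex/smoking as 0/1 indicators), or NULL.
#' @param micro_pcs matrix of microbial PC scores used as extra covariates,
#'   or NULL.
#' @param taxon,trait_name,level labels carried into the result.
#' @return one-row data.frame: level, taxon, trait, n, beta, se, t, p_nominal.
#' @export
fit_association <- function(taxon_abund, trait, covariates = NULL,
                            micro_pcs = NULL, taxon = "taxon",
                            trait_name = "trait", level = "genus") {
  n <- length(trait)
  stopifnot(length(taxon_abund) == n)
  X <- cbind(abund = taxon_abund, covariate_design(n, covariates, micro_pcs))
  f <- ols_term(as.numeric(trait), X, "abund")
  data.frame(level = level, taxon = taxon, trait = trait_name, n = f$n,
             beta = f$beta, se = f$se, t = f$t, p_nominal = f$p,
             stringsAsFactors = FALSE)
}

#' Univariate taxon x trait association scan
#'
#' Runs [fit_association] for every (taxon, trait) pair of a per-individual
#' CLR abundance matrix against a trait matrix. Taxon columns are
#' quantile-normalized once before the scan. If an effective-test count is
#' supplied, Sidak-corrected p-values are appended.
#'
#' @param clr_ind individuals x taxa matrix of (batch-corrected, averaged)
#'   CLR abundances; rownames identify individuals.
#' @param traits individuals x traits matrix, rows aligned with `clr_ind`.
#' @param covariates,micro_pcs as in [fit_association], aligned on rows.
#' @param m_eff optional `eff_tests` object (or count) used for the Sidak
#'   correction of the scan.
#' @param level taxonomy level label stored in the results.
#' @return data.frame with one row per pair (n_taxa x n_traits rows), columns
#'   level, taxon, trait, n, beta, se, t, p_nominal and, when `m_eff` is
#'   given, p_sidak. Failed fits are kept as rows with NA statistics and the
#'   error message in an `error` column (only present if any fit failed).
#' @export
assoc_scan <- function(clr_ind, traits, covariates = NULL, micro_pcs = NULL,
                       m_eff = NULL, level = "genus") {
  clr_ind <- as.matrix(clr_ind); traits <- as.matrix(traits)
  if (nrow(clr_ind) != nrow(traits)) stop("matrices not aligned on individuals")
  n <- nrow(clr_ind)
  qn <- apply(clr_ind, 2L, quantile_normalize)
  Z <- covariate_design(n, covariates, micro_pcs)
  taxa <- colnames(clr_ind); trs <- colnames(traits)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(ncol(clr_ind)))
  if (is.null(trs)) trs <- paste0("trait", seq_len(ncol(traits)))
  out <- vector("list", length(taxa) * length(trs))
  errs <- character(length(out)); k <- 0L
  for (i in seq_along(taxa)) {
    X <- cbind(abund = qn[, i], Z)
    for (j in seq_along(trs)) {
      k <- k + 1L
      f <- tryCatch(ols_term(traits[, j], X, "abund"), error = function(e) e)
      if (inherits(f, "error")) {
        errs[k] <- conditionMessage(f)
        f <- list(n = NA_integer_, beta = NA_real_, se = NA_real_,
                  t = NA_real_, p = NA_real_)
      }
      out[[k]] <- data.frame(level = level, taxon = taxa[i], trait = trs[j],
                             n = f$n, beta = f$beta, se = f$se, t = f$t,
                             p_nominal = f$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(nzchar(errs))) res$error <- errs
  if (!is.null(m_eff)) res$p_sidak <- sidak_correct(res$p_nominal, m_eff)
  res
}

#' Enrichment of nominally significant associations
#'
#' Exact one-sided binomial tail test of whether more than the expected
#' `alpha` fraction of association p-values fall below `alpha`:
#' P(X >= k | N, alpha) with k the observed count.
#'
#' @param results data.frame with a `p_nominal` column (e.g. from
#'   [assoc_scan]), or a numeric vector of p-values.
#' @param alpha nominal significance threshold (default 0.05).
#' @return list with `k` (count below alpha), `n` (tests), `p_binomial`.
#' @export
enrichment_test <- function(results, alpha = 0.05) {
  p <- if (is.data.frame(results)) results$p_nominal else as.numeric(results)
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied")
  k <- sum(p < alpha); n <- length(p)
  list(k = k, n = n,
       p_binomial = stats::pbinom(k - 1L, n, alpha, lower.tail = FALSE))
}

#' Polygenic-score instrumental-variable regression
#'
#' The Mendelian-randomization stage: linear regression of a
#' quantile-normalized taxon abundance on the polygenic score of a glycan
#' trait (the instrument), adjusted for covariates. A significant PRS term
#' supports a causal trait -> taxon interpretation.
#'
#' @param prs numeric vector of per-individual polygenic-score values.
#' @param taxon_abund per-individual taxon CLR abundance (quantile-normalized
#'   internally).
#' @param covariates as in [fit_association].
#' @param taxon,trait_name labels for the result.
#' @return one-row data.frame as in [fit_association] (beta is the PRS term).
#' @export
mr_stage <- function(prs, taxon_abund, covariates = NULL, taxon = "taxon",
                     trait_name = "trait") {
  stopifnot(length(prs) == length(taxon_abund))
  y <- quantile_normalize(taxon_abund)
  X <- cbind(prs = as.numeric(prs),
             covariate_design(length(y), covariates))
  f <- ols_term(y, X, "prs")
  data.frame(level = "genus", taxon = taxon, trait = trait_name, n = f$n,
             beta = f$beta, se = f$se, t = f$t, p_nominal = f$p,
             stringsAsFactors = FALSE)
}
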