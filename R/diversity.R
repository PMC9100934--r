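#' Shannon alpha diversity
#'
#' H = -sum p_i ln p_i (natural log) over the positive components of each
#' relative-abundance row.
#'
#' @param rel samples x taxa relative abundances (rows summing to 1).
#' @return named numeric vector of Shannon indices (nats).
#' @export
shannon_index <- function(rel) {
  rel <- as.matrix(rel)
  if (any(rel < 0)) stop("negative abundance")
  if (any(abs(rowSums(rel) - 1) > 1e-6))
    stop("rows must sum to 1 (relative abundances)")
  vegan::diversity(rel, index = "shannon")
}

#' Aitchison distance
#'
#' Euclidean distance between CLR-transformed profiles — the beta-diversity
#' geometry used throughout the pipeline.
#'
#' @param clrm samples x taxa CLR matrix.
#' @return a `dist` object.
#' @export
aitchison_dist <- function(clrm) stats::dist(as.matrix(clrm), method = "euclidean")

#' Permutational multivariate analysis of variance
#'
#' Anderson's pseudo-F on a distance matrix, with the permutation p-value
#' estimator (1 + #\{F_perm >= F_obs\}) / (1 + B). When `strata` is given,
#' labels are permuted within strata only (used when testing location while
#' blocking on technical structure).
#'
#' @param d a `dist` object (square symmetric distances).
#' @param grouping factor of group labels, one per sample.
#' @param B number of permutations (>= 99; default 9999).
#' @param seed integer seed for the permutation stream.
#' @param strata optional blocking factor for restricted permutations.
#' @return list with `f` (pseudo-F), `r2`, `p`, `b`, `seed`.
#' @export
permanova <- function(d, grouping, B = 9999, seed = 1L, strata = NULL) {
  stopifnot(inherits(d, "dist"), B >= 99)
  grouping <- factor(grouping)
  if (any(table(grouping) < 2L)) stop("every group needs at least 2 members")
  set.seed(seed)
  dat <- data.frame(grouping = grouping)
  fit <- vegan::adonis2(d ~ grouping, data = dat, permutations = B,
                        strata = strata)
  list(f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1], b = B, seed = seed)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with significance from
#' row/column co-permutation of one matrix.
#'
#' @param d1,d2 `dist` objects over the same samples.
#' @param B permutations (default 9999).
#' @param seed integer seed.
#' @return list with `r`, `p`, `b`, `seed`.
#' @export
mantel_test <- function(d1, d2, B = 9999, seed = 1L) {
  if (attr(d1, "Size") != attr(d2, "Size")) stop("distance matrices differ in size")
  set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = B)
  list(r = unname(fit$statistic), p = fit$signif, b = B, seed = seed)
}

#' Procrustes concordance test (protest)
#'
#' Optimal translation/rotation/scaling of one ordination onto another;
#' reports the Procrustes correlation sqrt(1 - m2), where m2 is the
#' minimized residual sum of squares fraction, with a row-permutation
#' p-value.
#'
#' @param X,Y score matrices (samples x retained PCs), rows aligned.
#' @param B permutations (default 9999).
#' @param seed integer seed.
#' @return list with `correlation`, `m2`, `p`, `b`, `seed`.
#' @export
procrustes_test <- function(X, Y, B = 9999, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("row counts differ")
  if (qr(X)$rank < ncol(X) || qr(Y)$rank < ncol(Y))
    stop("rank-deficient input scores")
  set.seed(seed)
  fit <- vegan::protest(X, Y, permutations = B)
  list(correlation = unname(fit$t0), m2 = unname(fit$ss), p = fit$signif,
       b = B, seed = seed)
}

## Shared engine: regress each trait on one predictor + covariates.
predictor_trait_scan <- function(pred_mat, traits, covariates, m_eff,
                                 pred_label) {
  res <- vector("list", ncol(pred_mat) * ncol(traits)); k <- 0L
  Z <- covariate_design(nrow(traits), covariates)
  for (i in seq_len(ncol(pred_mat))) {
    X <- cbind(pred = pred_mat[, i], Z)
    for (j in seq_len(ncol(traits))) {
      k <- k + 1L
      f <- ols_term(traits[, j], X, "pred")
      res[[k]] <- data.frame(predictor = colnames(pred_mat)[i] %||%
                               paste0(pred_label, i),
                             trait = colnames(traits)[j] %||% paste0("trait", j),
                             n = f$n, beta = f$beta, se = f$se, t = f$t,
                             p_nominal = f$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (!is.null(m_eff)) {
    m <- if (inherits(m_eff, "eff_tests")) m_eff$m_eff else m_eff
    out$m_tests <- m * ncol(pred_mat)
    out$p_sidak <- sidak_correct(out$p_nominal, m * ncol(pred_mat))
  }
  out
}

#' Alpha diversity vs glycan traits
#'
#' Regresses each glycan trait on the Shannon index plus covariates; Sidak
#' correction uses the effective number of glycome tests.
#'
#' @param h per-individual Shannon indices.
#' @param traits individuals x traits matrix, rows aligned with `h`.
#' @param covariates data.frame (age, sex, bmi, smoking), aligned.
#' @param m_eff_glycome effective glycome test count (`eff_tests` or number),
#'   or NULL to skip correction.
#' @return data.frame: predictor, trait, n, beta, se, t, p_nominal
#'   (+ m_tests, p_sidak).
#' @export
alpha_association <- function(h, traits, covariates = NULL,
                              m_eff_glycome = NULL) {
  pred <- matrix(as.numeric(h), ncol = 1, dimnames = list(NULL, "shannon"))
  predictor_trait_scan(pred, as.matrix(traits), covariates, m_eff_glycome,
                       "shannon")
}

#' Microbiome beta-diversity PCs vs glycan traits
#'
#' Regresses each glycan trait on each microbial principal component plus
#' covariates; the Sidak correction accounts for
#' M_eff(glycome) x (number of PCs) tests (e.g. 24 x 10 = 240).
#'
#' @param micro_pcs individuals x PCs score matrix (typically 10 PCs).
#' @param traits individuals x traits matrix, rows aligned.
#' @param covariates data.frame (age, sex, bmi, smoking), aligned.
#' @param m_eff_glycome effective glycome test count, or NULL.
#' @return data.frame, one row per (PC, trait) pair.
#' @export
beta_pc_association <- function(micro_pcs, traits, covariates = NULL,
                                m_eff_glycome = NULL) {
  predictor_trait_scan(as.matrix(micro_pcs), as.matrix(traits), covariates,
                       m_eff_glycome, "PC")
}
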