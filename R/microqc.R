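#' Impute zero counts by the taxon's minimal observed fraction
#'
#' Converts a count table to relative abundances and replaces every zero cell
#' of a taxon by that taxon's minimum positive relative abundance over all
#' libraries, then renormalizes each row to sum to 1. This keeps the table
#' strictly positive so a log-ratio transformation is defined.
#'
#' @param counts non-negative matrix, libraries x taxa. Each taxon must have
#'   at least one positive count (all-zero taxa should have been removed by
#'   the abundance filter).
#' @return relative-abundance matrix of the same shape, rows summing to 1.
#' @export
impute_zeros <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  zero_tax <- colSums(counts) == 0
  if (any(zero_tax))
    stop("taxa with all-zero counts (remove first): ",
         paste(colnames(counts)[zero_tax], collapse = ", "))
  rel <- counts / rowSums(counts)
  minpos <- apply(rel, 2L, function(v) min(v[v > 0]))
  zero <- rel == 0
  rel[zero] <- rep(minpos, each = nrow(rel))[zero]
  rel / rowSums(rel)
}

#' Centered log-ratio transformation
#'
#' Per row, log(x_i) - mean_i log(x_i) (natural log). Rows of the result sum
#' to zero (CLR closure).
#'
#' @param rel strictly positive matrix, rows are compositions.
#' @return matrix of CLR values with the same dimnames.
#' @export
clr_transform <- function(rel) {
  rel <- as.matrix(rel)
  if (any(rel <= 0)) {
    bad <- which(rel <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive entry at row ", rownames(rel)[bad[1]] %||% bad[1],
         ", column ", colnames(rel)[bad[2]] %||% bad[2])
  }
  lx <- log(rel)
  sweep(lx, 1L, rowMeans(lx), "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Align per-individual covariates onto a library-level sample table.
library_covariates <- function(samples, covariates) {
  need <- c("age", "sex", "bmi", "smoking")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  i <- match(samples$individual_id, covariates$individual_id)
  if (anyNA(i)) stop("covariates missing for individual(s): ",
                     paste(unique(samples$individual_id[is.na(i)]), collapse = ", "))
  covariates[i, need, drop = FALSE]
}

## Multi-response OLS on a common design: residual sums of squares, and
## coefficient/t-p for one named column. Aliased columns are dropped.
mlm_fit <- function(X, Y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    X <- X[, keep, drop = FALSE]
    qx <- qr(X)
  }
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  list(X = X, qr = qx, beta = beta, rss = colSums(res^2),
       df = nrow(X) - qx$rank, rank = qx$rank)
}

#' Rule-based contaminant detection on CLR abundances
#'
#' Classifies genera as putative contaminants using four rules applied to
#' CLR-transformed abundances (zeros imputed by the minimal-fraction rule):
#' \describe{
#'   \item{R1}{significant negative dependence on coverage depth
#'     (Benjamini-Hochberg adjusted p < `alpha` and a negative coverage
#'     coefficient);}
#'   \item{R2}{low consistency across biological replicates
#'     (Spearman r < `r2_threshold`);}
#'   \item{R3}{moderately low replicate consistency (r < `r3_threshold`)
#'     AND the genus is not on the gut-resident allowlist;}
#'   \item{R4}{significant run discordance (BH-adjusted ANOVA p < `alpha` of
#'     the run x amplicon-within-location term) AND not on the allowlist.}
#' }
#' The per-taxon linear model has explanatory variables age, sex, BMI,
#' smoking status, collection date, location, amplicon, run x amplicon nested
#' in location, and log10 coverage; R1 uses the coverage term's t-test (set
#' `depth_mode = "spearman"` for a marginal Spearman correlation instead) and
#' R4 the F-test of the run term. BH adjustment is applied within each rule
#' across taxa. Replicate consistency is the Spearman correlation of CLR
#' values pooled over replicate pairs, evaluated only for taxa with nonzero
#' raw counts in at least `min_replicate_prevalence` of the replicate
#' libraries; with no replicates R2/R3 are reported as not evaluable, never
#' as hits. Negative-control libraries are excluded from all fits.
#'
#' @param counts integer matrix, libraries x taxa (no all-zero taxa).
#' @param samples library metadata data.frame (see [simulate_microbiome]).
#' @param covariates per-individual data.frame with age, sex, bmi, smoking.
#' @param allowlist character vector of genera characteristic for the human
#'   gut (see [gut_allowlist]); rules R3/R4 never fire for these.
#' @param alpha BH-adjusted significance level for R1/R4 (default 0.05).
#' @param r2_threshold,r3_threshold replicate-consistency cutoffs
#'   (defaults 0.3, 0.4).
#' @param depth_mode "model" (coverage term of the linear model, default) or
#'   "spearman" (marginal correlation).
#' @param min_replicate_prevalence minimum fraction of replicate libraries
#'   with a nonzero count for R2/R3 to be evaluable (default 0.5).
#' @param min_replicate_count minimum mean read count over replicate
#'   libraries for R2/R3 to be evaluable (default 10): below ~10 reads the
#'   log-abundance of a taxon is dominated by counting noise and replicate
#'   consistency is uninformative.
#' @return data.frame of class `contaminant_report`, one row per taxon:
#'   statistics (cov_stat, cov_p, cov_p_bh, replicate_r, run_p, run_p_bh),
#'   logical rule hits R1..R4, `replicate_evaluable`, and the `contaminant`
#'   verdict (TRUE iff any rule fires).
#' @export
detect_contaminants <- function(counts, samples, covariates, allowlist,
                                alpha = 0.05, r2_threshold = 0.3,
                                r3_threshold = 0.4,
                                depth_mode = c("model", "spearman"),
                                min_replicate_prevalence = 0.5,
                                min_replicate_count = 10) {
  depth_mode <- match.arg(depth_mode)
  counts <- as.matrix(counts)
  keep <- !samples$negative_control
  samples <- samples[keep, , drop = FALSE]
  counts <- counts[samples$library_id, , drop = FALSE]
  taxa <- colnames(counts)
  Y <- clr_transform(impute_zeros(counts))

  cv <- library_covariates(samples, covariates)
  df <- data.frame(cv,
                   collection_date = factor(samples$collection_date),
                   location = factor(samples$location),
                   amplicon = factor(samples$amplicon),
                   run = factor(samples$run),
                   log_cov = log10(samples$coverage))
  X_full <- stats::model.matrix(
    ~ age + sex + bmi + smoking + collection_date + location + amplicon +
      location:amplicon:run + log_cov, df)
  X_norun <- stats::model.matrix(
    ~ age + sex + bmi + smoking + collection_date + location + amplicon +
      log_cov, df)

  full <- mlm_fit(X_full, Y)
  norun <- mlm_fit(X_norun, Y)

  ## R1: coverage-depth dependence
  j <- match("log_cov", colnames(full$X))
  pp <- order(full$qr$pivot)
  XtXinv <- chol2inv(qr.R(full$qr))[pp, pp, drop = FALSE]
  cov_coef <- full$beta[j, ]
  cov_se <- sqrt(full$rss / full$df * XtXinv[j, j])
  cov_t <- cov_coef / cov_se
  cov_p <- 2 * stats::pt(abs(cov_t), full$df, lower.tail = FALSE)
  cov_stat <- cov_coef
  if (depth_mode == "spearman") {
    rel <- counts / rowSums(counts)
    sp <- apply(rel, 2L, function(v)
      stats::cor.test(v, samples$coverage, method = "spearman", exact = FALSE))
    cov_stat <- vapply(sp, function(s) unname(s$estimate), 0)
    cov_p <- vapply(sp, function(s) s$p.value, 0)
  }
  cov_p_bh <- bh_adjust(cov_p)
  r1 <- cov_p_bh < alpha & cov_stat < 0

  ## R4: run discordance (F-test of the run term, added last)
  q <- full$rank - norun$rank
  Fstat <- ((norun$rss - full$rss) / q) / (full$rss / full$df)
  run_p <- stats::pf(Fstat, q, full$df, lower.tail = FALSE)
  run_p_bh <- bh_adjust(run_p)
  r4 <- run_p_bh < alpha & !(taxa %in% allowlist)

  ## R2/R3: replicate consistency
  rep_r <- rep(NA_real_, length(taxa))
  evaluable <- rep(FALSE, length(taxa))
  grp <- samples$replicate_group
  groups <- split(seq_len(nrow(samples)), grp)
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  if (length(groups) >= 3L) {
    prs <- do.call(rbind, lapply(groups, function(ix)
      t(utils::combn(ix, 2L))))
    lib_ix <- unique(as.vector(prs))
    prev <- colMeans(counts[lib_ix, , drop = FALSE] > 0)
    mean_ct <- colMeans(counts[lib_ix, , drop = FALSE])
    evaluable <- prev >= min_replicate_prevalence &
      mean_ct >= min_replicate_count
    a <- Y[prs[, 1], , drop = FALSE]; b <- Y[prs[, 2], , drop = FALSE]
    rep_r <- vapply(seq_along(taxa), function(t)
      suppressWarnings(stats::cor(a[, t], b[, t], method = "spearman")), 0)
    rep_r[!evaluable] <- NA_real_
  }
  r2 <- !is.na(rep_r) & rep_r < r2_threshold
  r3 <- !is.na(rep_r) & rep_r < r3_threshold & !(taxa %in% allowlist)

  out <- data.frame(taxon = taxa, cov_stat = unname(cov_stat),
                    cov_p = unname(cov_p), cov_p_bh = unname(cov_p_bh),
                    replicate_r = unname(rep_r),
                    replicate_evaluable = unname(evaluable),
                    run_p = unname(run_p), run_p_bh = unname(run_p_bh),
                    R1 = unname(r1), R2 = unname(r2), R3 = unname(r3),
                    R4 = unname(r4), stringsAsFactors = FALSE)
  out$contaminant <- out$R1 | out$R2 | out$R3 | out$R4
  rownames(out) <- NULL
  class(out) <- c("contaminant_report", "data.frame")
  out
}

#' Recall and precision of contaminant rules against planted truth
#'
#' For each planted mechanism, recall is the fraction of its taxa hit by the
#' mechanism's characteristic rule (depth_inverse -> R1,
#' replicate_inconsistent -> R2, run_specific -> R4); precision counts a
#' rule hit as a true positive if the taxon is any planted contaminant (a
#' depth-inverse contaminant legitimately also fails replicate consistency).
#'
#' @param report a `contaminant_report`.
#' @param truth the `truth` element of a [simulate_microbiome] result.
#' @return data.frame with mechanism, rule, recall, precision, n_planted,
#'   n_flagged.
#' @export
contaminant_metrics <- function(report, truth) {
  map <- c(depth_inverse = "R1", replicate_inconsistent = "R2",
           run_specific = "R4")
  all_planted <- unlist(truth$contaminant_taxa, use.names = FALSE)
  out <- lapply(names(map), function(mech) {
    rule <- map[[mech]]
    planted <- truth$contaminant_taxa[[mech]]
    hit <- report$taxon[report[[rule]] %in% TRUE]
    data.frame(mechanism = mech, rule = rule,
               recall = if (length(planted)) mean(planted %in% hit) else NA_real_,
               precision = if (length(hit)) mean(hit %in% all_planted) else NA_real_,
               n_planted = length(planted), n_flagged = length(hit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Coverage and abundance filtering
#'
#' Applies, in order: removal of contaminant taxa (from a
#' [detect_contaminants] report), removal of libraries below the
#' amplicon-specific coverage threshold (>= 10,000 reads for V1V2 and V5V6,
#' >= 5,000 for V3V4), and removal of taxa whose mean relative abundance is
#' below `abundance_threshold` in at least one (mode "any", the default) or
#' in every (mode "all") location x amplicon stratum.
#'
#' @param counts libraries x taxa count matrix.
#' @param samples library metadata aligned by library_id.
#' @param report optional `contaminant_report`; flagged taxa are dropped.
#' @param coverage_thresholds named vector of minimum coverage per amplicon.
#' @param abundance_threshold relative-abundance cutoff (default 1e-4,
#'   i.e. 0.01%).
#' @param mode "any" or "all" (see above).
#' @return list with the filtered `counts` and matching `samples`.
#' @export
filter_libraries_and_taxa <- function(counts, samples, report = NULL,
                                      coverage_thresholds = c(V1V2 = 10000,
                                                              V3V4 = 5000,
                                                              V5V6 = 10000),
                                      abundance_threshold = 1e-4,
                                      mode = c("any", "all")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (!is.null(report)) {
    drop_tax <- report$taxon[report$contaminant]
    counts <- counts[, !(colnames(counts) %in% drop_tax), drop = FALSE]
  }
  thr <- coverage_thresholds[samples$amplicon]
  if (anyNA(thr)) stop("no coverage threshold for amplicon(s): ",
                       paste(unique(samples$amplicon[is.na(thr)]), collapse = ", "))
  keep_lib <- samples$coverage >= thr
  samples <- samples[keep_lib, , drop = FALSE]
  counts <- counts[samples$library_id, , drop = FALSE]
  if (!nrow(counts)) stop("no data after filtering")
  rel <- counts / rowSums(counts)
  stratum <- interaction(samples$location, samples$amplicon, drop = TRUE)
  mean_by <- rowsum(rel, stratum) / as.vector(table(stratum))
  low <- mean_by < abundance_threshold
  drop_tax <- if (mode == "any") apply(low, 2L, any) else apply(low, 2L, all)
  counts <- counts[, !drop_tax, drop = FALSE]
  if (!ncol(counts) || !nrow(counts)) stop("no data after filtering")
  rownames(samples) <- NULL
  list(counts = counts, samples = samples)
}

#' Mixed-model batch correction of CLR abundances
#'
#' Per taxon, fits (by REML) the linear mixed model
#' `clr ~ location + amplicon + location:amplicon:run + (1 | collection_date)`
#' and returns the observed values minus all fitted fixed batch terms and the
#' predicted date random intercept, plus the taxon's grand mean — i.e. the
#' model residual re-centered on the original mean. When the random-effect
#' variance is estimated at the boundary (singular fit) or the mixed fit
#' fails, the taxon falls back to ordinary least squares with collection date
#' as a fixed effect; aliased batch terms (e.g. a run with a single library)
#' are dropped automatically.
#'
#' @param clrm libraries x taxa CLR matrix.
#' @param samples library metadata aligned by library_id.
#' @return corrected CLR matrix of the same shape, with an attribute
#'   `ols_fallback` naming taxa corrected by the OLS fallback.
#' @export
batch_correct <- function(clrm, samples) {
  clrm <- as.matrix(clrm)
  i <- match(rownames(clrm), samples$library_id)
  if (anyNA(i)) stop("samples missing for some libraries")
  need <- c("run", "amplicon", "location", "collection_date")
  s <- samples[i, , drop = FALSE]
  if (anyNA(s[need])) stop("run/amplicon/location/collection_date required for every library")
  df <- data.frame(location = factor(s$location), amplicon = factor(s$amplicon),
                   run = factor(s$run),
                   collection_date = factor(s$collection_date))
  out <- clrm
  fallback <- character(0)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  for (t in seq_len(ncol(clrm))) {
    df$y <- clrm[, t]
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ location + amplicon + location:amplicon:run +
                     (1 | collection_date), data = df, REML = TRUE,
                   control = ctrl))),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
      fallback <- c(fallback, colnames(clrm)[t] %||% as.character(t))
      ols <- stats::lm(y ~ location + amplicon + location:amplicon:run +
                         collection_date, data = df)
      out[, t] <- stats::residuals(ols) + mean(df$y)
    } else {
      out[, t] <- as.numeric(stats::residuals(fit)) + mean(df$y)
    }
  }
  if (length(fallback))
    message("OLS fallback (singular mixed fit) for ", length(fallback), " taxa")
  attr(out, "ols_fallback") <- fallback
  out
}

#' Average the available profiles of each individual
#'
#' Per individual, the arithmetic mean of all available (batch-corrected)
#' location x amplicon CLR profiles — up to nine per individual; missing
#' libraries simply reduce the divisor.
#'
#' @param clrm libraries x taxa matrix.
#' @param samples library metadata aligned by library_id.
#' @return individuals x taxa matrix, rownames = individual ids.
#' @export
average_profiles <- function(clrm, samples) {
  clrm <- as.matrix(clrm)
  i <- match(rownames(clrm), samples$library_id)
  if (anyNA(i)) stop("samples missing for some libraries")
  ind <- samples$individual_id[i]
  keep <- !is.na(ind)
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " libraries without an individual")
    clrm <- clrm[keep, , drop = FALSE]; ind <- ind[keep]
  }
  n <- table(ind)
  rowsum(clrm, ind) / as.vector(n)
}

#' Principal component analysis with deterministic sign convention
#'
#' Centered (unscaled) PCA. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are reproducible across
#' platforms.
#'
#' @param x observations x variables matrix.
#' @param k number of components to return.
#' @return list with `scores` (n x k), `loadings` (p x k) and
#'   `variance_fractions` (over all components, summing to 1).
#' @export
microbial_pca <- function(x, k = 10L) {
  x <- as.matrix(x)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-9)
  if (k > rank) stop("k (", k, ") exceeds rank (", rank, ")")
  flip <- vapply(seq_len(k), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, TRUE)
  sc <- pr$x[, seq_len(k), drop = FALSE]
  ld <- pr$rotation[, seq_len(k), drop = FALSE]
  sc[, flip] <- -sc[, flip, drop = FALSE]
  ld[, flip] <- -ld[, flip, drop = FALSE]
  list(scores = sc, loadings = ld, variance_fractions = v / sum(v))
}
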