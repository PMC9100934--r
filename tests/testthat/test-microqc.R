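test_that("zero imputation uses the taxon's minimal positive fraction", {
  counts <- rbind(L1 = c(2, 1, 1), L2 = c(1, 0, 3), L3 = c(0, 2, 2))
  colnames(counts) <- c("t1", "t2", "t3")
  out <- impute_zeros(counts)
  ## hand computation: min positive fractions are 0.25 for every taxon;
  ## imputed rows renormalize from sum 1.25
  expect_equal(out["L1", ], c(t1 = 0.5, t2 = 0.25, t3 = 0.25), tolerance = 1e-12)
  expect_equal(out["L2", ], c(t1 = 0.2, t2 = 0.2, t3 = 0.6), tolerance = 1e-12)
  expect_equal(out["L3", ], c(t1 = 0.2, t2 = 0.4, t3 = 0.4), tolerance = 1e-12)

  nz <- rbind(c(3, 1), c(1, 1))
  expect_equal(impute_zeros(nz), nz / rowSums(nz), tolerance = 1e-12)
  expect_error(impute_zeros(cbind(a = c(1, 2), b = c(0, 0))), "b")
})

test_that("CLR transformation: closed form, closure and error reporting", {
  expect_equal(unname(clr_transform(matrix(rep(0.2, 5), 1))[1, ]), rep(0, 5))
  row <- matrix(c(0.5, 0.25, 0.25), 1)
  expect_equal(unname(clr_transform(row)[1, ]),
               c(2 * log(2) / 3, -log(2) / 3, -log(2) / 3), tolerance = 1e-12)
  set.seed(1)
  m <- matrix(runif(200, 0.01, 1), 20)
  m <- m / rowSums(m)
  expect_lt(max(abs(rowSums(clr_transform(m)))), 1e-12)
  bad <- matrix(c(0.5, 0, 0.5), 1, dimnames = list("s1", c("a", "b", "c")))
  expect_error(clr_transform(bad), "b")
})

test_that("coverage filter applies amplicon-specific thresholds at the stated boundaries", {
  counts <- matrix(100L, 4, 3,
                   dimnames = list(sprintf("L%02d", 1:4), c("t1", "t2", "t3")))
  samples <- toy_samples(4)
  samples$amplicon <- c("V3V4", "V3V4", "V1V2", "V1V2")
  samples$coverage <- c(5000L, 4999L, 10000L, 9999L)
  f <- filter_libraries_and_taxa(counts, samples, abundance_threshold = 0)
  expect_setequal(f$samples$library_id, c("L01", "L03"))
})

test_that("abundance filter drops taxa below 0.01% in any stratum", {
  ## 2 strata x 2 libraries; t4 at 0.005% and t5 absent in stratum A
  counts <- rbind(L01 = c(10000, 6000, 3999, 1, 0),
                  L02 = c(10000, 6000, 3999, 1, 0),
                  L03 = c(9000, 6000, 2000, 1500, 1500),
                  L04 = c(9000, 6000, 2000, 1500, 1500))
  colnames(counts) <- paste0("t", 1:5)
  samples <- toy_samples(4)
  samples$location <- c("ileum", "ileum", "rectum", "rectum")
  f <- filter_libraries_and_taxa(counts, samples)
  expect_setequal(colnames(f$counts), c("t1", "t2", "t3"))
  ## mode = "all" keeps taxa that are abundant somewhere
  f2 <- filter_libraries_and_taxa(counts, samples, mode = "all")
  expect_setequal(colnames(f2$counts), paste0("t", 1:5))
  ## filtering is a fixed point
  f3 <- filter_libraries_and_taxa(f$counts, f$samples)
  expect_identical(f3$counts, f$counts)
})

test_that("batch correction removes planted run structure and little else", {
  cfg <- tiny_cfg(seed = 21, n_taxa = 25, n_contaminants_per_mechanism = 0,
                  n_runs = 3, batch_effect_sd = 1.0)
  mb <- simulate_microbiome(cfg)
  clrm <- clr_transform(impute_zeros(mb$counts[, colSums(mb$counts) > 0]))
  bc <- batch_correct(clrm, mb$samples)
  cell <- factor(paste(mb$samples$run, mb$samples$location, mb$samples$amplicon))
  r2_run <- mean(vapply(seq_len(ncol(bc)), function(t)
    summary(lm(bc[, t] ~ cell))$r.squared, 0))
  expect_lt(r2_run, 0.01)

  ## no-op limit: with no structural effects every removed term is pure
  ## estimation noise, bounded by 3 standard errors of the fitted values
  cfg0 <- tiny_cfg(seed = 22, n_individuals = 50, n_taxa = 25,
                   n_contaminants_per_mechanism = 0, n_replicated_pairs = 0,
                   n_runs = 3, n_dates = 8, batch_effect_sd = 0,
                   sd_location = 0, sd_amplicon = 0, sd_date = 0)
  mb0 <- simulate_microbiome(cfg0)
  clr0 <- clr_transform(impute_zeros(mb0$counts[, colSums(mb0$counts) > 0]))
  bc0 <- batch_correct(clr0, mb0$samples)
  ## removed terms are estimation noise only; the per-individual averaged
  ## profiles the pipeline consumes must be preserved. Collection dates are
  ## confounded with individuals (~6 per date here), so the date term can
  ## absorb at most ~1/6 of the between-individual variance: expected
  ## attenuation of the per-taxon correlation is bounded by
  ## sqrt(1 - 1/6) ~ 0.91 up to cell-mean noise.
  a1 <- average_profiles(clr0, mb0$samples)
  a2 <- average_profiles(bc0, mb0$samples)
  rel0 <- mb0$counts / rowSums(mb0$counts)
  abundant <- colMeans(rel0[, colnames(clr0)]) >= 1e-3
  cc <- diag(cor(a1[, abundant], a2[, abundant]))
  expect_gt(sum(abundant), 5)
  expect_gt(mean(cc), 0.85)
  expect_gt(min(cc), 0.7)
})

test_that("batch correction is invariant to library order", {
  cfg <- tiny_cfg(seed = 23, n_individuals = 15, n_taxa = 12,
                  n_contaminants_per_mechanism = 0, n_runs = 3)
  mb <- simulate_microbiome(cfg)
  clrm <- clr_transform(impute_zeros(mb$counts[, colSums(mb$counts) > 0]))
  bc1 <- batch_correct(clrm, mb$samples)
  ix <- sample(nrow(clrm))
  bc2 <- batch_correct(clrm[ix, ], mb$samples)
  expect_equal(bc2[rownames(bc1), ], bc1, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("profile averaging: idempotence, symmetry and a hand-computed mean", {
  clrm <- rbind(L01 = c(1, 2), L02 = c(3, 4), L03 = c(5, 6))
  colnames(clrm) <- c("t1", "t2")
  samples <- toy_samples(3)
  samples$individual_id <- c("A", "A", "A")
  expect_equal(unname(average_profiles(clrm, samples)["A", ]), c(3, 4))

  clrm2 <- rbind(L01 = c(2, -1), L02 = c(-2, 1))
  colnames(clrm2) <- c("t1", "t2")
  s2 <- toy_samples(2); s2$individual_id <- c("B", "B")
  expect_equal(unname(average_profiles(clrm2, s2)["B", ]), c(0, 0))

  nine <- matrix(rep(c(1.5, -0.5), each = 9), 9, 2,
                 dimnames = list(sprintf("L%02d", 1:9), c("t1", "t2")))
  s9 <- toy_samples(9); s9$individual_id <- rep("C", 9)
  expect_equal(unname(average_profiles(nine, s9)["C", ]), c(1.5, -0.5))
})

test_that("PCA: variance fractions, rank handling and the eigen oracle", {
  set.seed(30)
  v <- rnorm(6)
  rank1 <- outer(rnorm(12), v)
  p1 <- microbial_pca(rank1, k = 1)
  expect_equal(p1$variance_fractions[1], 1, tolerance = 1e-9)
  expect_equal(sum(p1$variance_fractions), 1, tolerance = 1e-12)

  x <- matrix(rnorm(20), 5, 4)
  p <- microbial_pca(x, k = 3)
  ## oracle: eigendecomposition of the covariance matrix
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc), symmetric = TRUE)
  or_scores <- xc %*% ev$vectors[, 1:3]
  for (j in 1:3)
    expect_lt(min(max(abs(p$scores[, j] - or_scores[, j])),
                  max(abs(p$scores[, j] + or_scores[, j]))), 1e-9)
  expect_error(microbial_pca(x, k = 5), "rank")

  ## deterministic sign: largest-magnitude loading positive
  for (j in 1:3) {
    l <- p$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("contaminant report: verdict logic, allowlist protection and no-replicate case", {
  cfg <- tiny_cfg(seed = 31)
  mb <- simulate_microbiome(cfg)
  gly <- simulate_glycome(cfg, mb)
  cov <- simulate_covariates_prs(cfg, gly)$covariates
  rep <- detect_contaminants(mb$counts, mb$samples, cov, mb$truth$gut_allowlist)
  expect_identical(rep$contaminant, rep$R1 | rep$R2 | rep$R3 | rep$R4)
  ## allowlisted taxa can never fire R3/R4
  onlist <- rep$taxon %in% mb$truth$gut_allowlist
  expect_false(any(rep$R3[onlist] | rep$R4[onlist]))
  ## abundant clean taxa are replicate-consistent
  clean_abund <- rep$taxon %in% mb$truth$gut_allowlist[1:10]
  expect_true(all(rep$replicate_r[clean_abund] > 0.4, na.rm = TRUE))

  ## without replicates R2/R3 never fire and are flagged not-evaluable
  cfg0 <- tiny_cfg(seed = 32, n_replicated_pairs = 0)
  mb0 <- simulate_microbiome(cfg0)
  rep0 <- detect_contaminants(mb0$counts, mb0$samples, cov,
                              mb0$truth$gut_allowlist)
  expect_false(any(rep0$R2 | rep0$R3))
  expect_false(any(rep0$replicate_evaluable))
  expect_error(detect_contaminants(mb$counts, mb$samples,
                                   cov[, -2], mb$truth$gut_allowlist),
               "missing covariate")
})
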