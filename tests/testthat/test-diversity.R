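test_that("Shannon index: maximum entropy, degenerate case, closed form", {
  k <- 7
  u <- matrix(rep(1 / k, k), 1)
  expect_equal(unname(shannon_index(u)), log(k), tolerance = 1e-12)
  expect_equal(unname(shannon_index(matrix(c(1, 0, 0), 1))), 0)
  expect_equal(unname(shannon_index(matrix(c(0.5, 0.25, 0.25), 1))),
               1.5 * log(2), tolerance = 1e-12)
  expect_error(shannon_index(matrix(c(-0.1, 1.1), 1)), "negative")
})

test_that("Aitchison distances are a valid metric on CLR profiles", {
  set.seed(1)
  m <- matrix(runif(60, 0.01, 1), 10)
  m <- m / rowSums(m)
  d <- as.matrix(aitchison_dist(clr_transform(m)))
  expect_equal(diag(d), rep(0, 10), ignore_attr = TRUE)
  expect_equal(d, t(d), tolerance = 1e-12)
  for (i in 1:20) {
    tr <- sample(10, 3)
    expect_lte(d[tr[1], tr[3]], d[tr[1], tr[2]] + d[tr[2], tr[3]] + 1e-12)
  }
})

test_that("PERMANOVA separates planted groups and bounds its p-value", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60), 15), matrix(rnorm(60, mean = 4), 15))
  g <- rep(c("a", "b"), each = 15)
  res <- permanova(dist(x), g, B = 999, seed = 5)
  expect_equal(res$p, 1 / 1000)  # the permutation minimum 1/(B+1)
  expect_gt(res$f, 10)
  expect_error(permanova(dist(x), c("a", rep("b", 29)), B = 99), "2 members")
})

test_that("PERMANOVA p-values are calibrated under the null", {
  set.seed(3)
  ps <- replicate(40, {
    x <- matrix(rnorm(80), 20)
    permanova(dist(x), sample(rep(c("a", "b"), 10)), B = 99,
              seed = sample.int(1e6, 1))$p
  })
  ## permutation p-values are discrete; use a binned goodness-of-fit check
  counts <- table(cut(ps, breaks = seq(0, 1, 0.25)))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
  expect_true(all(ps >= 1 / 100))
})

test_that("Mantel statistic: identity, affine invariance, null behavior", {
  set.seed(4)
  x <- matrix(rnorm(100), 20)
  d1 <- dist(x)
  expect_equal(mantel_test(d1, d1, B = 99, seed = 1)$r, 1, tolerance = 1e-12)
  d2 <- as.dist(3 * as.matrix(d1) + 2); attr(d2, "Size") <- attr(d1, "Size")
  expect_equal(mantel_test(d1, d2, B = 99, seed = 1)$r, 1, tolerance = 1e-12)

  ok <- replicate(20, {
    a <- dist(matrix(rnorm(90), 30))
    b <- dist(matrix(rnorm(90), 30))
    res <- mantel_test(a, b, B = 199, seed = sample.int(1e6, 1))
    abs(res$r) < 0.3 && res$p > 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("Procrustes correlation: perfect rotation, bounds, independence", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  th <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  res <- procrustes_test(X, X %*% R, B = 199, seed = 1)
  expect_equal(res$correlation, 1, tolerance = 1e-9)
  expect_lt(res$m2, 1e-12)

  Y <- matrix(rnorm(60), 20, 3)
  r2 <- procrustes_test(X, Y, B = 199, seed = 2)
  expect_gte(r2$correlation, 0)
  expect_lte(r2$correlation, 1)
  expect_gt(r2$p, 0.01)
  expect_error(procrustes_test(X, cbind(Y[, 1], Y[, 1], Y[, 2])), "rank")
})

test_that("beta-diversity PC scan recovers a planted PC-trait link and counts tests", {
  set.seed(6)
  n <- 80
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  tr <- matrix(rnorm(n * 24), n, 24,
               dimnames = list(NULL, paste0("T", 1:24)))
  tr[, 7] <- tr[, 7] + 1.2 * pcs[, 6]
  res <- beta_pc_association(pcs, tr, m_eff_glycome = 24)
  expect_equal(unique(res$m_tests), 240)
  best <- res[which.min(res$p_nominal), ]
  expect_equal(c(best$predictor, best$trait), c("PC6", "T7"))
  expect_true(all(res$p_sidak >= res$p_nominal))
})

test_that("alpha-diversity scan reports one row per trait with Sidak correction", {
  set.seed(7)
  n <- 60
  h <- rnorm(n, 2, 0.3)
  tr <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("T", 1:5)))
  tr[, 2] <- tr[, 2] - 0.9 * scale(h)[, 1]
  res <- alpha_association(h, tr, m_eff_glycome = 5)
  expect_equal(nrow(res), 5L)
  expect_equal(res$trait[which.min(res$p_nominal)], "T2")
  expect_lt(res$beta[res$trait == "T2"], 0)
})
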