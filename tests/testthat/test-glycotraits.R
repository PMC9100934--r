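test_that("shipped map and registry satisfy their structural invariants", {
  map <- read_harmonization_map()
  expect_equal(nrow(map), 39L)
  expect_equal(length(unique(map$gp)), 36L)
  expect_equal(anyDuplicated(map$peak), 0L)

  reg <- read_trait_registry()
  expect_equal(nrow(reg), 81L)
  expect_equal(anyDuplicated(reg$name), 0L)
  gps <- unique(map$gp)
  refs <- unique(unlist(c(reg$numerator, reg$repertoire, reg$denominator)))
  expect_true(all(refs %in% gps))
})

test_that("harmonization sums mapped peaks and conserves total area", {
  toy <- matrix(c(1, 2, 3, 4), 1, dimnames = list("s1", c("a", "b", "c", "d")))
  map <- data.frame(peak = c("a", "b", "c", "d"), gp = c("X", "X", "Y", "Z"))
  expect_equal(harmonize_peaks(toy, map),
               matrix(c(3, 3, 4), 1, dimnames = list("s1", c("X", "Y", "Z"))))

  idmap <- data.frame(peak = c("a", "b"), gp = c("a", "b"))
  m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(harmonize_peaks(m, idmap), m)

  set.seed(1)
  peaks <- matrix(runif(10 * 39), 10, 39,
                  dimnames = list(NULL, sprintf("P%d", 1:39)))
  gp <- harmonize_peaks(peaks)
  expect_equal(rowSums(gp), rowSums(peaks), tolerance = 1e-12)
  expect_equal(ncol(gp), 36L)

  bad <- matrix(1, 1, 2, dimnames = list(NULL, c("P1", "Pxx")))
  expect_error(harmonize_peaks(bad), "Pxx")
})

test_that("total-area normalization closes rows and rejects empty chromatograms", {
  expect_equal(unname(total_area_normalize(matrix(c(2, 2, 4), 1))[1, ]),
               c(0.25, 0.25, 0.5))
  set.seed(2)
  x <- matrix(runif(60), 6)
  n1 <- total_area_normalize(x)
  expect_equal(total_area_normalize(n1), n1, tolerance = 1e-12)
  expect_equal(rowSums(n1), rep(1, 6), tolerance = 1e-12)
  z <- rbind(s1 = c(1, 1), s2 = c(0, 0))
  expect_error(total_area_normalize(z), "s2")
})

test_that("derived traits follow their compositional transformations", {
  comp <- matrix(rep(0.25, 4), 1, dimnames = list("s", paste0("GP", 1:4)))
  mk <- function(class, num, rep = character(0), den = character(0)) {
    data.frame(name = "x", class = class,
               numerator = I(list(num)), repertoire = I(list(rep)),
               denominator = I(list(den)))
  }
  ## MERGE_CLR on uniform 4-part with a 2-part numerator: (0.5,.25,.25)
  v <- derive_trait(comp, mk("MERGE_CLR", c("GP1", "GP2")))
  expect_equal(unname(v), 2 * log(2) / 3, tolerance = 1e-12)

  ## RATIO_ILR symmetry -> 0; closed form otherwise
  expect_equal(unname(derive_trait(comp, mk("RATIO_ILR", c("GP1", "GP2"),
                                            den = c("GP3", "GP4")))), 0)
  r <- derive_trait(comp, mk("RATIO_ILR", "GP1", den = c("GP2", "GP3")))
  expect_equal(unname(r), log(0.5) / sqrt(2), tolerance = 1e-12)

  ## SUBCOMP_CLR is invariant to rescaling the repertoire by a common factor
  set.seed(3)
  c2 <- matrix(runif(8, 0.05, 1), 2, 4,
               dimnames = list(NULL, paste0("GP", 1:4)))
  def <- mk("SUBCOMP_CLR", "GP1", rep = c("GP1", "GP2", "GP3"))
  a <- derive_trait(c2, def)
  c3 <- c2; c3[, c("GP1", "GP2", "GP3")] <- 7 * c3[, c("GP1", "GP2", "GP3")]
  expect_equal(derive_trait(c3, def), a, tolerance = 1e-12)

  expect_error(derive_trait(comp, mk("MERGE_CLR", paste0("GP", 1:4))),
               "whole composition")
  expect_error(derive_trait(comp, mk("MERGE_CLR", "GP9")), "GP9")
})

test_that("trait matrix has 117 columns and is scale-invariant per sample", {
  set.seed(4)
  peaks <- matrix(runif(5 * 39, 0.1, 2), 5, 39,
                  dimnames = list(sprintf("I%d", 1:5), sprintf("P%d", 1:39)))
  gp <- harmonize_peaks(peaks)
  tr <- compute_traits(gp)
  expect_equal(ncol(tr), 117L)
  expect_equal(as.vector(table(attr(tr, "provenance"))[c("original", "derived")]),
               c(36L, 81L))
  ## multiplying all raw areas of one sample by c leaves every trait unchanged
  gp2 <- gp; gp2[3, ] <- 5.5 * gp2[3, ]
  expect_equal(compute_traits(gp2)[3, ], tr[3, ], tolerance = 1e-12)
})

test_that("original-trait CLR closes rows and matches a direct computation", {
  u <- matrix(rep(1 / 36, 36), 1, dimnames = list(NULL, sprintf("GP%d", 1:36)))
  expect_equal(unname(original_trait_clr(u)[1, ]), rep(0, 36))
  set.seed(5)
  x <- matrix(runif(36, 0.01, 1), 1, dimnames = list(NULL, sprintf("GP%d", 1:36)))
  x <- x / sum(x)
  got <- original_trait_clr(x)[1, ]
  expect_equal(unname(got), unname(log(x[1, ]) - mean(log(x[1, ]))),
               tolerance = 1e-12)
  expect_lt(abs(sum(got)), 1e-12)
})
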