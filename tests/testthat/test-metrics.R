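test_that("overlap metrics satisfy their identities and count arithmetic", {
  set.seed(10)
  m <- array(as.numeric(array(rnorm(10^3), c(10, 10, 10)) > 0.4),
             c(10, 10, 10))
  a <- label_map(m)
  self <- overlap_metrics(a, a)
  expect_equal(c(self$dsc, self$precision, self$recall), c(1, 1, 1))

  b <- label_map(1 - m)
  disj <- overlap_metrics(a, b)
  expect_equal(c(disj$dsc, disj$precision, disj$recall), c(0, 0, 0))

  # pred covers half of ref with no false positives
  ref <- array(0, c(8, 8, 8)); ref[1:4, , ] <- 1
  pred <- array(0, c(8, 8, 8)); pred[1:2, , ] <- 1
  half <- overlap_metrics(label_map(pred), label_map(ref))
  expect_equal(half$dsc, 2 / 3)
  expect_equal(half$precision, 1)
  expect_equal(half$recall, 0.5)

  empty <- overlap_metrics(label_map(array(0, c(4, 4, 4))),
                           label_map(array(0, c(4, 4, 4))))
  expect_equal(empty$dsc, 1)
})

test_that("overlap metrics are invariant under joint translation", {
  set.seed(11)
  base <- array(0, c(12, 12, 12))
  base[3:6, 4:7, 5:8] <- 1
  pred <- array(0, c(12, 12, 12))
  pred[3:5, 4:7, 5:8] <- 1
  m0 <- overlap_metrics(label_map(pred), label_map(base))
  shift <- function(x) {
    y <- array(0, dim(x)); y[4:7, 5:8, 6:9] <- x[3:6, 4:7, 5:8]; y
  }
  m1 <- overlap_metrics(label_map(shift(pred)), label_map(shift(base)))
  expect_equal(m0$dsc, m1$dsc)
  expect_equal(m0$precision, m1$precision)
})

test_that("mean surface distance is 0 on identical masks and d on parallel slabs", {
  m <- array(0, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- 1
  a <- label_map(m, spacing = c(0.5, 0.5, 0.5))
  expect_equal(msd(a, a), 0)

  slab <- function(z) {
    x <- array(0, c(10, 10, 12)); x[, , z] <- 1
    label_map(x, spacing = c(0.5, 0.5, 0.5))
  }
  expect_equal(msd(slab(3), slab(8)), 2.5, tolerance = 1e-9)
  expect_equal(msd(slab(3), slab(8)), msd(slab(8), slab(3)))
  expect_error(msd(a, label_map(array(0, c(8, 8, 8)),
                                spacing = c(0.5, 0.5, 0.5))), "empty")
})

test_that("odds ratios reproduce the printed contingency tables", {
  smoking <- odds_ratio(60, 55, 105, 51)
  expect_equal(round(smoking$or, 2), 0.53)
  expect_lt(smoking$p, 0.05)
  age <- odds_ratio(114, 76, 51, 30)
  expect_equal(round(age$or, 2), 0.88)
  balanced <- odds_ratio(20, 20, 20, 20)
  expect_equal(balanced$or, 1)
  # reciprocal under exposure flip
  f <- odds_ratio(55, 60, 51, 105)
  expect_equal(smoking$or * f$or, 1, tolerance = 1e-12)
  zero <- odds_ratio(5, 0, 3, 2)
  expect_false(zero$defined)
  expect_true(is.na(zero$or))
})

test_that("Mann-Whitney U uses exact enumeration for tiny samples", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  # exact and approximate p agree within 0.02 at the n = 8 boundary
  set.seed(12)
  x <- rnorm(8); y <- rnorm(8, 1)
  exact_p <- mann_whitney(x, y)$p
  approx_p <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE)$p.value)
  expect_lt(abs(exact_p - approx_p), 0.02)
})

test_that("one-way ANOVA, Shapiro gate and Pearson behave at their edges", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  an <- anova_oneway(g)
  expect_equal(an$f, 0, tolerance = 1e-12)
  expect_error(anova_oneway(list(c(1, 2, 3))), "two groups")
  expect_error(anova_oneway(list(c(1, 2), c(3, 4))), ">= 3")

  expect_error(shapiro_gate(rep(1, 10)), "constant")
  set.seed(13)
  sg <- shapiro_gate(rnorm(50))
  expect_true(sg$normal)

  x <- c(1, 2, 3, 5, 8)
  pc <- pearson_cor(x, x)
  expect_equal(pc$r, 1)
  expect_error(pearson_cor(x, rep(2, 5)), "constant")
})

test_that("Bland-Altman computes bias and limits of agreement", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))

  shifted <- bland_altman(c(1, 2, 3), c(6, 7, 8))
  expect_equal(shifted$bias, -5)
  expect_equal(shifted$loa_low, -5)
  expect_equal(shifted$loa_high, -5)

  a <- c(10, 12, 17); b <- c(9, 14, 15)
  d <- a - b
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(c(1, 2), c(1, 2, 3)), "equal length")
})
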