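# Inter-rater agreement statistics.

test_that("percent agreement is the exact-match proportion", {
  expect_equal(percent_agreement(letters[1:6], letters[1:6]), 1)
  expect_equal(percent_agreement(c(1, 1, 2, 2), c(1, 2, 2, 1)), 0.5)
  # 428 matches of 464 item-presence comparisons -> 92.2%
  x <- rep(c(TRUE, FALSE), c(300, 164))
  y <- x; y[1:36] <- !y[1:36]
  expect_equal(percent_agreement(x, y), 428 / 464)
  expect_equal(round(100 * percent_agreement(x, y), 1), 92.2)
  expect_error(percent_agreement(1:3, 1:4), "equal length")
})

test_that("kappa matches the hand-worked 2x2 example", {
  tab <- matrix(c(45, 5, 5, 45), 2, byrow = TRUE)
  k <- cohens_kappa(tab)
  expect_equal(k$estimate, 0.8)       # p_o = 0.9, p_e = 0.5
  expect_equal(k$po, 0.9)
  expect_equal(k$pe, 0.5)
  expect_lt(k$ci_low, 0.8)
  expect_gt(k$ci_high, 0.8)
  expect_lt(k$p_value, 0.001)
})

test_that("perfect agreement with >= 2 categories gives kappa 1, CI (1, 1)", {
  x <- rep(c("prod_a", "prod_b", "prod_c"), c(100, 80, 38))
  k <- cohens_kappa(x, x)
  expect_equal(k$estimate, 1)
  expect_equal(k$ci_low, 1)
  expect_equal(k$ci_high, 1)
  expect_equal(k$n, 218L)
})

test_that("independent raters give kappa near zero", {
  set.seed(101)
  x <- sample(letters[1:3], 10000, TRUE)
  y <- sample(letters[1:3], 10000, TRUE)
  expect_lt(abs(cohens_kappa(x, y)$estimate), 0.05)
})

test_that("degenerate single-category tables follow the stated conventions", {
  # perfect agreement, one observed category: 1 with a warning
  expect_warning(k <- cohens_kappa(rep("a", 10), rep("a", 10)), "degenerate")
  expect_equal(k$estimate, 1)
  # one rater constant: chance-corrected agreement collapses to 0
  tab <- matrix(c(5, 5, 0, 0), 2, byrow = TRUE)
  expect_equal(cohens_kappa(tab)$estimate, 0)
})

test_that("weighted kappa with identity weights equals unweighted kappa", {
  set.seed(102)
  x <- sample(1:4, 80, TRUE)
  y <- ifelse(runif(80) < 0.6, x, sample(1:4, 80, TRUE))
  ku <- cohens_kappa(x, y)
  ki <- weighted_kappa(x, y, levels = as.character(1:4), scheme = "identity")
  expect_equal(ki$estimate, ku$estimate, tolerance = 1e-12)
  expect_equal(ki$ci_low, ku$ci_low, tolerance = 1e-12)
})

test_that("weighted kappa matches direct weighted summation on a 3x3 table", {
  tab <- matrix(c(10, 2, 0, 2, 10, 2, 0, 2, 10), 3, byrow = TRUE)
  for (scheme in c("linear", "quadratic")) {
    kw <- weighted_kappa(tab, scheme = scheme)
    expect_equal(kw$estimate, bf_kappa(tab, bf_weights(3, scheme)),
                 tolerance = 1e-12, info = scheme)
  }
  # perfect ordinal agreement
  kp <- weighted_kappa(diag(c(5, 6, 7)), scheme = "linear")
  expect_equal(kp$estimate, 1)
})

test_that("on two categories all weighting schemes coincide", {
  set.seed(103)
  x <- sample(c("lo", "hi"), 60, TRUE)
  y <- ifelse(runif(60) < 0.7, x, sample(c("lo", "hi"), 60, TRUE))
  lv <- c("lo", "hi")
  k0 <- cohens_kappa(x, y)$estimate
  expect_equal(weighted_kappa(x, y, lv, "linear")$estimate, k0,
               tolerance = 1e-12)
  expect_equal(weighted_kappa(x, y, lv, "quadratic")$estimate, k0,
               tolerance = 1e-12)
})

test_that("kappa is invariant under category relabeling", {
  set.seed(104)
  x <- sample(letters[1:4], 100, TRUE)
  y <- ifelse(runif(100) < 0.5, x, sample(letters[1:4], 100, TRUE))
  relab <- c(a = "z", b = "q", c = "m", d = "f")
  expect_equal(cohens_kappa(relab[x], relab[y])$estimate,
               cohens_kappa(x, y)$estimate, tolerance = 1e-12)
  # order-preserving relabeling for the ordinal statistic
  x2 <- sample(1:3, 100, TRUE)
  y2 <- ifelse(runif(100) < 0.5, x2, sample(1:3, 100, TRUE))
  expect_equal(
    weighted_kappa(x2, y2, levels = as.character(1:3))$estimate,
    weighted_kappa(c("low", "mid", "high")[x2], c("low", "mid", "high")[y2],
                   levels = c("low", "mid", "high"))$estimate,
    tolerance = 1e-12)
})

test_that("ICC is 1 for a duplicated column and near 0 for pure noise", {
  set.seed(105)
  m <- cbind(rnorm(10, 5), 0)
  m[, 2] <- m[, 1]
  expect_equal(icc_two_way_random(m, "single")$estimate, 1, tolerance = 1e-9)
  noise <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(icc_two_way_random(noise, "single")$estimate), 0.1)
})

test_that("ICC matches the aov mean-squares oracle on a toy matrix", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2, byrow = TRUE)
  o <- bf_icc(m)
  expect_equal(icc_two_way_random(m, "single")$estimate, o$single,
               tolerance = 1e-12)
  expect_equal(icc_two_way_random(m, "average")$estimate, o$average,
               tolerance = 1e-12)
})

test_that("average-rater ICC is at least the single-rater ICC", {
  set.seed(106)
  for (i in 1:10) {
    m <- matrix(rnorm(24, 10, 2), 8, 3) + rnorm(8, 0, 2)
    s <- icc_two_way_random(m, "single")$estimate
    a <- icc_two_way_random(m, "average")$estimate
    if (s >= 0) expect_gte(a + 1e-12, s)
  }
})

test_that("ICC rejects degenerate inputs", {
  expect_error(icc_two_way_random(matrix(3, 4, 2)), "variance")
  expect_error(icc_two_way_random(matrix(1:4, 1, 4)), "at least 2 subjects")
  m <- matrix(c(1, 2, NA, 4), 2, 2)
  expect_error(icc_two_way_random(m), "complete")
})

test_that("square-root transform handles edge cases", {
  expect_equal(sqrt_transform(c(0, 1, 4, 9)), c(0, 1, 2, 3))
  expect_equal(sqrt_transform(numeric(0)), numeric(0))
  expect_equal(sqrt_transform(2), sqrt(2))
  expect_error(sqrt_transform(-1), "non-negative")
})

test_that("interpretation bands reproduce the published labels", {
  expect_equal(interpret_agreement(0.88, "kappa"), "very good")
  expect_equal(interpret_agreement(0.70, "kappa"), "good")
  expect_equal(interpret_agreement(0.50, "kappa"), "moderate")
  # published kappa band list places "fair" below "poor"
  expect_equal(interpret_agreement(0.10, "kappa"), "fair")
  expect_equal(interpret_agreement(0.30, "kappa"), "poor")
  expect_equal(interpret_agreement(0.10, "kappa", bands = "conventional"),
               "poor")
  expect_equal(interpret_agreement(0.30, "kappa", bands = "conventional"),
               "fair")
  expect_equal(interpret_agreement(0.934, "icc"), "excellent")
  expect_equal(interpret_agreement(0.30, "icc"), "poor")
  expect_equal(interpret_agreement(0.50, "icc"), "fair")
  expect_equal(interpret_agreement(0.70, "icc"), "good")
  expect_error(interpret_agreement(1.2, "kappa"), "exceed 1")
})
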