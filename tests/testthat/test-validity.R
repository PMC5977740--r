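# Validity pipeline pieces: sales preprocessing, truncation,
# correlations, sequential regression, collinearity screening.

test_that("weekly least-healthy sales halve a two-week total per channel", {
  sales <- data.frame(
    item = c("cola soft drink", "chocolate bar", "bottled water",
             "potato chips"),
    channel = c("concession", "concession", "concession", "vending"),
    dollars = c(120, 80, 50, 60))
  out <- weekly_least_healthy_sales(sales)
  expect_equal(out$weekly[["concession"]], 100)  # (120 + 80) / 2
  expect_equal(out$weekly[["vending"]], 30)
  expect_length(out$excluded_channels, 0)
})

test_that("all-most-healthy sales give zero dollars per week", {
  sales <- data.frame(item = c("bottled water", "fresh fruit cup"),
                      channel = "concession", dollars = c(40, 20))
  out <- weekly_least_healthy_sales(sales)
  expect_equal(out$weekly[["concession"]], 0)
})

test_that("unclassifiable rows flag their channel excluded", {
  sales <- data.frame(
    item = c("cola soft drink", "misc item #9"),
    channel = c("concession", "concession"),
    dollars = c(100, 10))
  out <- weekly_least_healthy_sales(sales)
  expect_true(is.na(out$weekly[["concession"]]))
  expect_equal(out$excluded_channels, "concession")
  expect_equal(nrow(out$unclassified), 1L)
  expect_error(
    weekly_least_healthy_sales(data.frame(item = "cola soft drink",
                                          channel = "kiosk", dollars = 5)),
    "unknown sales channel")
})

test_that("truncation replaces values beyond z SD by next-closest plus one", {
  # hand-computed: mean 17.54, sd (incl. outlier) 26.09, z = 2 ->
  # threshold 69.7; 100 -> max inlier 12, replaced by 12 + 1 = 13
  x <- c(8, 9, 10, 10, 11, 12, 9, 10, 11, 10, 10.5, 100)
  out <- truncate_outliers(x, z = 2)
  expect_equal(out$values[12], 13)
  expect_equal(out$log$original, 100)
  expect_equal(out$log$replacement, 13)
  expect_equal(out$values[-12], x[-12])
})

test_that("truncation leaves in-range data unchanged and is idempotent", {
  set.seed(201)
  x <- rnorm(30, 50, 5)
  out <- truncate_outliers(x)
  expect_equal(out$values, x)
  expect_equal(nrow(out$log), 0L)
  # with a genuine outlier, a second pass changes nothing
  y <- c(rnorm(20, 50, 5), 500)
  once <- truncate_outliers(y)
  expect_gt(nrow(once$log), 0)
  twice <- truncate_outliers(once$values)
  expect_equal(twice$values, once$values)
  expect_equal(nrow(twice$log), 0L)
})

test_that("tied outliers are replaced identically", {
  y <- c(rep(c(5, 6, 7), 8), 400, 400)
  out <- truncate_outliers(y)
  expect_equal(unique(out$values[25:26]), 8)  # max inlier 7 + 1
})

test_that("no value at n = 5 can sit beyond 3 sample SD", {
  # the largest achievable z-score with n points is (n-1)/sqrt(n)
  x <- c(1, 2, 3, 4, 1000)
  out <- truncate_outliers(x, z = 3)
  expect_equal(out$values, x)
  expect_equal(nrow(out$log), 0L)
})

test_that("correlations recover exact and residualized relationships", {
  x <- 1:12
  y <- 2 * x
  out <- correlations(x, y)
  expect_equal(out$pearson$estimate, 1, tolerance = 1e-12)
  # with an empty control set, partial equals pearson
  set.seed(202)
  x <- rnorm(20); y <- x + rnorm(20)
  out <- correlations(x, y)
  expect_equal(out$partial$estimate, out$pearson$estimate, tolerance = 1e-12)
  expect_error(correlations(rep(1, 10), rnorm(10)), "constant")
})

test_that("partial correlation equals the residual-oracle identity", {
  set.seed(203)
  z1 <- rnorm(12); z2 <- rnorm(12)
  x <- 0.5 * z1 - z2 + rnorm(12)
  y <- -z1 + 0.3 * z2 + rnorm(12)
  ctrl <- data.frame(z1 = z1, z2 = z2)
  out <- correlations(x, y, controls = ctrl)
  rx <- resid(lm(x ~ z1 + z2))
  ry <- resid(lm(y ~ z1 + z2))
  expect_equal(out$partial$estimate, cor(rx, ry), tolerance = 1e-10)
  # p-value consistent with the t transform at n - 2 - q df
  r <- out$partial$estimate
  tt <- r * sqrt(8) / sqrt(1 - r^2)
  expect_equal(out$partial$p_value, 2 * pt(-abs(tt), 8), tolerance = 1e-12)
})

test_that("sequential regression reports exact nested-model quantities", {
  set.seed(204)
  z <- rnorm(20)
  y <- 3 * z  # outcome exactly linear in block 1
  fit <- suppressWarnings(
    sequential_regression(y, data.frame(z = z), data.frame(w = rnorm(20))))
  expect_equal(fit$models$model1$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$models$model2$delta_r_squared, 0, tolerance = 1e-10)
})

test_that("orthogonal blocks decompose R2 additively", {
  n <- 32
  z <- scale(rep(c(-1, 1), n / 2))[, 1]
  w <- scale(rep(c(-1, 1), each = n / 2))[, 1]
  expect_lt(abs(cor(z, w)), 1e-12)
  set.seed(205)
  y <- z + 2 * w + rnorm(n, 0, 0.5)
  full <- sequential_regression(y, data.frame(z = z), data.frame(w = w))
  solo <- summary(lm(y ~ w))$r.squared
  expect_equal(full$models$model2$delta_r_squared, solo, tolerance = 1e-10)
})

test_that("F-change matches the direct sum-of-squares computation", {
  set.seed(206)
  d <- data.frame(z = rnorm(20), w = rnorm(20))
  y <- 0.5 * d$z + 0.8 * d$w + rnorm(20)
  fit <- sequential_regression(y, d["z"], d["w"])
  m1 <- lm(y ~ z, data = d); m2 <- lm(y ~ z + w, data = d)
  ss1 <- sum(resid(m1)^2); ss2 <- sum(resid(m2)^2)
  f_direct <- ((ss1 - ss2) / 1) / (ss2 / (20 - 2 - 1))
  expect_equal(fit$models$model2$f_change, f_direct, tolerance = 1e-10)
  expect_equal(fit$models$model2$p_change,
               pf(f_direct, 1, 17, lower.tail = FALSE), tolerance = 1e-12)
  # nested R2 monotonicity
  expect_gte(fit$models$model2$r_squared, fit$models$model1$r_squared)
  expect_gte(fit$models$model2$delta_r_squared, 0)
})

test_that("rank-deficient designs name the collinear column", {
  set.seed(207)
  z <- rnorm(15)
  expect_error(
    sequential_regression(rnorm(15), data.frame(z = z),
                          data.frame(z2 = 2 * z)),
    "rank-deficient.*z2")
})

test_that("collinearity screen flags pairs and recommends the right drop", {
  set.seed(208)
  a <- rnorm(40)
  b <- rnorm(40)
  expect_equal(nrow(collinearity_screen(data.frame(a = a, b = b), rnorm(40))),
               0L)
  # duplicated predictor: |r| = 1
  scr <- collinearity_screen(data.frame(a = a, a2 = a), rnorm(40))
  expect_equal(abs(scr$r), 1)
  # collinear pair where only one member predicts the outcome: build
  # x2 = 0.8 u + 0.6 v and y with a v-loading that cancels x2's
  # association while keeping cor(x1, x2) around 0.8
  n <- 40
  u <- scale(rnorm(n))[, 1]
  v <- scale(resid(lm(rnorm(n) ~ u)))[, 1]
  x1 <- u
  x2 <- 0.8 * u + 0.6 * v
  y <- u - (0.8 / 0.6) * v + rnorm(n, 0, 0.3)
  scr <- collinearity_screen(data.frame(x1 = x1, x2 = x2), y)
  expect_equal(nrow(scr), 1L)
  expect_gt(abs(scr$r), 0.7)
  expect_equal(scr$drop, "x2")
})

test_that("the pipeline recovers a score-coupled sponsorship signal", {
  p <- generator_params()
  audits <- generate_audits(p, seed = 301)
  oc <- generate_outcomes(audits, p, seed = 302)
  rep <- run_validity_pipeline(oc)
  expect_gt(rep$sponsorship$food$partial$estimate, 0)
  expect_lt(rep$sponsorship$food$partial$p_value, 0.05)
  expect_gt(rep$regressions$concession$models$model2$delta_r_squared, 0)
})

test_that("pipeline refuses tiny tables and skips absent sections", {
  p <- generator_params(n_sites = 3L)
  oc <- generate_outcomes(generate_audits(p, 303), p, 304)
  expect_error(run_validity_pipeline(oc), "at least 10 sites")
  # all sponsorship missing: section skipped with a log entry
  p2 <- generator_params(p_missing_sponsorship = 1)
  oc2 <- generate_outcomes(generate_audits(p2, 305), p2, 306)
  rep <- run_validity_pipeline(oc2)
  expect_null(rep$sponsorship)
  expect_true(any(grepl("sponsorship", rep$log)))
})

test_that("missing-data t-tests compare provided vs withheld sites", {
  p <- generator_params()
  oc <- generate_outcomes(generate_audits(p, 307), p, 308)
  rep <- run_validity_pipeline(oc)
  md <- rep$missing_data$food_sponsorship
  expect_equal(md$n_present + md$n_missing, nrow(oc))
  expect_true(md$p_value >= 0 && md$p_value <= 1)
})
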