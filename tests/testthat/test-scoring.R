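# Site scoring: exposure, power, repetition, totals.

test_that("area frequency counts occasions and triggered pricing in food", {
  occ <- rbind(occ_row(), occ_row(item = 2L), occ_row(item = 3L))
  a <- site_audit("s1", occ)
  expect_equal(area_frequency(a, "food"), 3L)
  expect_equal(area_frequency(a, "sport"), 0L)
  expect_equal(area_frequency(site_audit("empty"), "food"), 0L)
  b <- site_audit("s1", occ, pricing_records(1:3, c(TRUE, TRUE, FALSE)))
  expect_equal(area_frequency(b, "food"), 5L)
  expect_equal(area_frequency(b, "sport"), 0L)
})

test_that("power profiles are proportions over the area's occasions", {
  occ <- rbind(occ_row(health = "least_healthy"),
               occ_row(item = 2L, health = "least_healthy"),
               occ_row(item = 3L, health = "most_healthy"),
               occ_row(item = 4L, health = "less_healthy"))
  a <- site_audit("s1", occ)
  p <- power_profile(a, "food")
  expect_equal(p$p_least, 0.5)
  expect_equal(p$p_less, 0.25)
  # empty area: all-zero profile
  p0 <- power_profile(a, "sport")
  expect_equal(unlist(p0), c(p_least = 0, p_less = 0, p_child = 0,
                             p_sport = 0, mean_size = 0, n = 0))
})

test_that("mean size averages only occasions that carry a size", {
  occ <- rbind(occ_row(size = "large"), occ_row(item = 2L, size = "small"),
               occ_row(item = 3L, size = NA_character_))
  a <- site_audit("s1", occ)
  expect_equal(power_profile(a, "food")$mean_size, 0.5)
})

test_that("unclassified occasions stop scoring with a named area", {
  a <- site_audit("s1", occ_row(health = NA_character_))
  expect_error(power_profile(a, "food"), "area 'food'.*occasion 1")
  expect_error(foodmats_score(a), "classif")
})

test_that("repetition counts distinct entities at the site-wide threshold", {
  three <- rbind(occ_row(), occ_row(item = 2L), occ_row(item = 3L))
  expect_equal(repetition_count(site_audit("s1", three)), 1L)
  two <- three[1:2, ]
  expect_equal(repetition_count(site_audit("s1", two)), 0L)
  expect_equal(repetition_count(site_audit("s1")), 0L)
  expect_error(repetition_count(site_audit("s1"), threshold = 1L), ">= 2")
})

test_that("splitting an entity's occasions across areas leaves R unchanged", {
  together <- rbind(occ_row(), occ_row(item = 2L), occ_row(item = 3L))
  split3 <- rbind(occ_row(area = "food"),
                  occ_row(area = "sport", item = 12L),
                  occ_row(area = "other", item = 20L))
  expect_equal(repetition_count(site_audit("s1", together)),
               repetition_count(site_audit("s1", split3)))
})

test_that("hand-evaluated area scores match the default weights", {
  # 1 occasion, most healthy, no flags, small size -> A = 1
  a <- site_audit("s1", occ_row(health = "most_healthy", size = "small"))
  expect_equal(area_score(a, "food"), 1)
  # 1 occasion, least healthy, child, sport, large -> A = 1*(1+1+1+1+1) = 5
  b <- site_audit("s1", occ_row(health = "least_healthy", child = TRUE,
                                sport = TRUE, size = "large"))
  expect_equal(area_score(b, "food"), 5)
  expect_equal(area_score(site_audit("e"), "food"), 0)
})

test_that("hand-evaluated site totals match", {
  expect_equal(foodmats_score(site_audit("e"))$total, 0)
  a <- site_audit("s1", occ_row(health = "most_healthy", size = "small"))
  expect_equal(foodmats_score(a)$total, 1)
  # 3 identical least/child/sport/large occasions of one brand in food:
  # 3*5 area points + 2*1 repetition = 17
  occ <- rbind(occ_row(child = TRUE, sport = TRUE, size = "large"),
               occ_row(item = 2L, child = TRUE, sport = TRUE, size = "large"),
               occ_row(item = 3L, child = TRUE, sport = TRUE, size = "large"))
  s <- foodmats_score(site_audit("s1", occ))
  expect_equal(s$total, 17)
  expect_equal(s$repetition_count, 1L)
})

test_that("total decomposes as area scores plus weighted repetition", {
  set.seed(41)
  for (i in 1:25) {
    a <- random_audit(sample(0:12, 1))
    cfg <- scoring_config(w_repetition = sample(0:3, 1))
    s <- foodmats_score(a, cfg)
    expect_equal(s$total,
                 sum(s$area_scores) + cfg$w_repetition * s$repetition_count)
    expect_gte(s$total, 0)
    expect_identical(s$total == 0,
                     nrow(a$occasions) == 0L && !any(a$pricing$triggered))
  }
})

test_that("appending any occasion never decreases the total", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_audit(sample(0:8, 1))
    extra <- random_audit(1)$occasions
    b <- site_audit("s1", rbind(a$occasions, extra), a$pricing)
    expect_gte(foodmats_score(b)$total, foodmats_score(a)$total)
  }
})

test_that("upgrading any power attribute never decreases the total", {
  set.seed(43)
  for (i in 1:20) {
    a <- random_audit(sample(1:8, 1))
    j <- sample(nrow(a$occasions), 1)
    base <- foodmats_score(a)$total
    b <- a; b$occasions$health_class[j] <- "least_healthy"
    expect_gte(foodmats_score(b)$total, base)
    b <- a; b$occasions$child_targeted[j] <- TRUE
    expect_gte(foodmats_score(b)$total, base)
    b <- a; b$occasions$sports_related[j] <- TRUE
    expect_gte(foodmats_score(b)$total, base)
    if (!is.na(a$occasions$size_class[j])) {
      b <- a; b$occasions$size_class[j] <- "large"
      expect_gte(foodmats_score(b)$total, base)
    }
  }
})

test_that("with all power and repetition weights zero, total = occasion count", {
  cfg <- scoring_config(w_content = 0, w_child = 0, w_sport = 0,
                        w_size = 0, w_repetition = 0)
  set.seed(44)
  for (i in 1:15) {
    a <- random_audit(sample(0:10, 1))
    expect_equal(foodmats_score(a, cfg)$total,
                 nrow(a$occasions) + sum(a$pricing$triggered))
  }
})

test_that("site totals match the brute-force oracle on small audits", {
  set.seed(45)
  for (i in 1:40) {
    a <- random_audit(sample(0:6, 1))
    cfg <- scoring_config(w_content = runif(1, 0, 2),
                          w_child = runif(1, 0, 2),
                          w_sport = runif(1, 0, 2),
                          w_size = runif(1, 0, 2),
                          w_less_fraction = runif(1),
                          w_repetition = runif(1, 0, 3))
    expect_equal(foodmats_score(a, cfg)$total, bf_site_score(a, cfg),
                 tolerance = 1e-12)
  }
})

test_that("invalid scoring configurations are rejected", {
  expect_error(scoring_config(w_content = -1), "non-negative")
  expect_error(scoring_config(w_less_fraction = 1.5), "\\[0, 1\\]")
  expect_error(scoring_config(repetition_threshold = 1), ">= 2")
})
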