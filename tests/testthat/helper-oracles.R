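# Independent brute-force oracles and fixture builders. Everything here
# deliberately uses explicit loops / aov() rather than the package's own
# code paths, so tests compare two independent computations.

## ---- agreement oracles -------------------------------------------------

# Kappa by direct cell-by-cell summation with an agreement-weight matrix.
bf_kappa <- function(tab, V = diag(nrow(tab))) {
  n <- sum(tab)
  k <- nrow(tab)
  po <- 0; pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      po <- po + V[i, j] * tab[i, j] / n
      pe <- pe + V[i, j] * (sum(tab[i, ]) / n) * (sum(tab[, j]) / n)
    }
  }
  (po - pe) / (1 - pe)
}

bf_weights <- function(k, scheme) {
  V <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      d <- abs(i - j) / (k - 1)
      V[i, j] <- switch(scheme,
                        identity = as.numeric(i == j),
                        linear = 1 - d,
                        quadratic = 1 - d^2)
    }
  }
  V
}

# Two-way random ICC via aov() mean squares (independent of the
# package's closed-form sums of squares).
bf_icc <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(y = as.vector(mat),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  list(single = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
       average = (msr - mse) / (msr + (msc - mse) / n))
}

## ---- scoring oracle ----------------------------------------------------

# Direct summation over occasions for small audits: loops only, no reuse
# of the package's area helpers. Every occasion contributes
# 1 + content + child + sport + size points; triggered pricing
# indicators contribute 1 + content as Least-Healthy pseudo-occasions in
# the food area.
bf_site_score <- function(audit, config = scoring_config()) {
  total <- 0
  size_points <- c(small = 0, medium = 0.5, large = 1)
  for (r in seq_len(nrow(audit$occasions))) {
    o <- audit$occasions[r, ]
    contrib <- 1
    if (o$health_class == "least_healthy") contrib <- contrib + config$w_content
    if (o$health_class == "less_healthy") {
      contrib <- contrib + config$w_content * config$w_less_fraction
    }
    if (o$child_targeted) contrib <- contrib + config$w_child
    if (o$sports_related) contrib <- contrib + config$w_sport
    if (!is.na(o$size_class)) {
      contrib <- contrib + config$w_size * size_points[[o$size_class]]
    }
    total <- total + contrib
  }
  for (r in seq_len(nrow(audit$pricing))) {
    if (audit$pricing$triggered[r]) {
      total <- total + 1 + config$w_content
    }
  }
  counts <- list()
  for (r in seq_len(nrow(audit$occasions))) {
    key <- paste(audit$occasions$entity_name[r],
                 audit$occasions$entity_kind[r])
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  reps <- sum(vapply(counts, function(x) x >= config$repetition_threshold,
                     logical(1)))
  total + config$w_repetition * reps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- fixture builders ----------------------------------------------------

# A quick single-entity occasion row.
occ_row <- function(site = "s1", area = "food", item = 1L,
                    entity = "Fizz Cola", kind = "brand",
                    health = "least_healthy", child = FALSE,
                    sport = FALSE, size = NA_character_,
                    setting = "indoor") {
  marketing_occasions(site, area, item, entity, kind, health, child,
                      sport, size, setting)
}

# Random classified audit for property tests.
random_audit <- function(n_occ, site = "s1") {
  if (n_occ == 0L) return(site_audit(site))
  occ <- marketing_occasions(
    site,
    area = sample(area_levels(), n_occ, TRUE),
    item_id = sample(1:26, n_occ, TRUE),
    entity_name = sample(paste0("e", 1:4), n_occ, TRUE),
    entity_kind = sample(entity_kinds(), n_occ, TRUE),
    health_class = sample(health_levels(), n_occ, TRUE),
    child_targeted = runif(n_occ) < 0.4,
    sports_related = runif(n_occ) < 0.4,
    size_class = ifelse(runif(n_occ) < 0.2, NA_character_,
                        sample(size_levels(), n_occ, TRUE)),
    setting = sample(setting_levels(), n_occ, TRUE)
  )
  pr <- pricing_records(1:11, runif(11) < 0.2)
  site_audit(site, occ, pr)
}

# Enumerate all multisets (non-decreasing index tuples) of sizes 1..kmax
# over `m` occasion types.
enumerate_multisets <- function(m, kmax) {
  out <- list()
  grow <- function(prefix, lo) {
    for (i in lo:m) {
      tup <- c(prefix, i)
      out[[length(out) + 1L]] <<- tup
      if (length(tup) < kmax) grow(tup, i)
    }
  }
  grow(integer(0), 1L)
  out
}
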