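## Seeded synthetic-data generator: audits, rater pairs, and
## sponsorship/sales outcomes with known ground-truth structure. The
## defaults emulate the study conditions of a ~50-site recreation-facility
## audit: one concession per site as the norm, a median of about three
## sports areas, occasion counts tied to facility size, a marketing mix
## dominated by Least Healthy content, and sponsorship/sales outcomes
## coupled to the score on the square-root scale (the scale on which the
## analyses transform both scores and dollars).

#' Generator parameters
#'
#' All knobs of the synthetic-audit generator with their documented
#' defaults. Occasion counts per area are Poisson; the food-area rate
#' scales with the number of concessions and the sport-area rate with the
#' number of sports areas, so that scores correlate with facility size as
#' observed in real facilities. Entity names are drawn from a rank-skewed
#' pool (probability proportional to 1/rank^skew) so that repetition at
#' the 3-recording threshold occurs at a controllable rate.
#'
#' @param n_sites Number of sites (default 50).
#' @param lambda_food Food-area occasions per concession (default 5).
#' @param lambda_sport Sport-area occasions per sports area (default 1.2).
#' @param lambda_other Other-area occasions per site (default 4).
#' @param health_mix Probabilities over (most, less, least) healthy
#'   (default 0.15/0.25/0.60: most recorded marketing is Least Healthy).
#' @param p_child,p_sport Design-flag probabilities (defaults 0.20, 0.25).
#' @param size_mix Probabilities over (small, medium, large)
#'   (default 0.3/0.5/0.2).
#' @param p_size_missing Probability an occasion has no size recorded
#'   (default 0.1; size is excluded for some pricing/place occasions).
#' @param p_outdoor Probability of an outdoor setting (default 0.2).
#' @param entity_pool Number of distinct entities (default 20).
#' @param entity_skew Zipf exponent of entity reuse (default 1).
#' @param p_pricing_trigger Probability each of the 11 pricing indicators
#'   is triggered (default 0.3).
#' @param rater_flip Per-attribute disagreement probability for the
#'   second rater (default 0.05).
#' @param spon_alpha,spon_beta,spon_sd Food-sponsorship model:
#'   sqrt(dollars) = alpha + beta * sqrt(score) + N(0, sd), floored at 0
#'   (defaults 2, 5, 4.5).
#' @param other_spon_mean,other_spon_sd Score-independent component of
#'   total sponsorship on the sqrt scale (defaults 100, 30), which
#'   attenuates the total-sponsorship correlation.
#' @param gamma0,gamma_sports,gamma_score,sales_sd Concession-sales model:
#'   sqrt(dollars/week) = g0 + g_sports * n_sports_areas +
#'   g_score * sqrt(score) + N(0, sd) (defaults 5, 2, 4, 5).
#' @param vend0,vend_sports,vend_score,vend_sd Vending-sales model
#'   (defaults 3, 1.5, 1.5, 4): a weaker coupling than concessions.
#' @param p_missing_sponsorship,p_missing_concession,p_missing_vending
#'   Per-site probabilities of not providing each outcome (defaults 0.3,
#'   0.4, 0.5, near the provision rates seen in practice).
#' @return A list of class \code{generator_params}.
#' @export
generator_params <- function(n_sites = 50L,
                             lambda_food = 5, lambda_sport = 1.2,
                             lambda_other = 4,
                             health_mix = c(most_healthy = 0.15,
                                            less_healthy = 0.25,
                                            least_healthy = 0.60),
                             p_child = 0.20, p_sport = 0.25,
                             size_mix = c(small = 0.3, medium = 0.5,
                                          large = 0.2),
                             p_size_missing = 0.1, p_outdoor = 0.2,
                             entity_pool = 20L, entity_skew = 1,
                             p_pricing_trigger = 0.3,
                             rater_flip = 0.05,
                             spon_alpha = 2, spon_beta = 5, spon_sd = 4.5,
                             other_spon_mean = 100, other_spon_sd = 30,
                             gamma0 = 5, gamma_sports = 2, gamma_score = 4,
                             sales_sd = 5,
                             vend0 = 3, vend_sports = 1.5, vend_score = 1.5,
                             vend_sd = 4,
                             p_missing_sponsorship = 0.3,
                             p_missing_concession = 0.4,
                             p_missing_vending = 0.5) {
  check_mix <- function(m, what, k) {
    if (length(m) != k || any(m < 0) || any(m > 1) ||
        abs(sum(m) - 1) > 1e-8) {
      stop(what, " must be ", k, " probabilities summing to 1", call. = FALSE)
    }
  }
  check_mix(health_mix, "health_mix", 3L)
  check_mix(size_mix, "size_mix", 3L)
  probs <- c(p_child = p_child, p_sport = p_sport,
             p_size_missing = p_size_missing, p_outdoor = p_outdoor,
             p_pricing_trigger = p_pricing_trigger, rater_flip = rater_flip,
             p_missing_sponsorship = p_missing_sponsorship,
             p_missing_concession = p_missing_concession,
             p_missing_vending = p_missing_vending)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment())[setdiff(names(formals()), "")],
            class = "generator_params")
}

zipf_weights <- function(pool, skew) {
  w <- (seq_len(pool))^(-skew)
  w / sum(w)
}

#' Generate synthetic site audits
#'
#' Draws per-site facility-size covariates, Poisson occasion counts per
#' area with means tied to facility size, and occasion attributes from
#' the configured mixtures. The seed fully determines the output.
#'
#' @param params A [generator_params()] list.
#' @param seed Integer RNG seed.
#' @return A list of \code{site_audit} objects of length
#'   \code{params$n_sites}.
#' @export
generate_audits <- function(params = generator_params(), seed = 1L) {
  set.seed(seed)
  ew <- zipf_weights(params$entity_pool, params$entity_skew)
  entity_names <- sprintf("entity_%02d", seq_len(params$entity_pool))
  entity_kind_pool <- rep(entity_kinds(), length.out = params$entity_pool)
  item_ranges <- list(food = 1:9, sport = 10:18, other = 19:26)

  lapply(seq_len(params$n_sites), function(i) {
    sid <- sprintf("site_%03d", i)
    n_conc <- 1L + stats::rbinom(1, 2, 0.15)
    n_sport <- 1L + stats::rpois(1, 2.5)
    lam <- c(food = params$lambda_food * n_conc,
             sport = params$lambda_sport * n_sport,
             other = params$lambda_other)
    counts <- stats::rpois(3, lam)
    names(counts) <- area_levels()
    total <- sum(counts)
    if (total == 0L) {
      occ <- empty_occasions()
    } else {
      area <- rep(area_levels(), counts)
      eidx <- sample.int(params$entity_pool, total, replace = TRUE, prob = ew)
      size <- sample(size_levels(), total, replace = TRUE,
                     prob = params$size_mix)
      size[stats::runif(total) < params$p_size_missing] <- NA_character_
      occ <- marketing_occasions(
        site_id = sid,
        area = area,
        item_id = vapply(area, function(a) {
          r <- item_ranges[[a]]
          r[sample.int(length(r), 1L)]
        }, integer(1)),
        entity_name = entity_names[eidx],
        entity_kind = entity_kind_pool[eidx],
        health_class = sample(health_levels(), total, replace = TRUE,
                              prob = params$health_mix),
        child_targeted = stats::runif(total) < params$p_child,
        sports_related = stats::runif(total) < params$p_sport,
        size_class = size,
        setting = ifelse(stats::runif(total) < params$p_outdoor,
                         "outdoor", "indoor")
      )
    }
    pr <- pricing_records(
      1:11, stats::runif(11) < params$p_pricing_trigger)
    site_audit(sid, occ, pr, n_concessions = n_conc,
               n_sports_areas = n_sport)
  })
}

#' Generate a two-rater audit pair
#'
#' Rater 1 records the audit exactly as given (the ground truth); rater 2
#' records the same occasions but each categorical or boolean attribute
#' (entity, healthfulness, child flag, sports flag, size) is independently
#' perturbed with probability \code{flip}: booleans are toggled,
#' categories are replaced by one of the other categories uniformly.
#'
#' @param audit A \code{site_audit}.
#' @param flip Per-attribute disagreement probability in [0, 1).
#' @param seed Integer RNG seed.
#' @param entity_pool Entity names available for entity perturbation
#'   (defaults to those present in the audit).
#' @return A list of two \code{rater_audit} objects.
#' @export
generate_rater_pair <- function(audit, flip = 0.05, seed = 1L,
                                entity_pool = NULL) {
  stopifnot(inherits(audit, "site_audit"))
  if (flip < 0 || flip >= 1) stop("flip must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  occ2 <- audit$occasions
  n <- nrow(occ2)
  if (n > 0L && flip > 0) {
    flip_cat <- function(x, levels_) {
      hit <- stats::runif(length(x)) < flip
      if (any(hit)) {
        x[hit] <- vapply(x[hit], function(v) {
          alt <- setdiff(levels_, v)
          alt[sample.int(length(alt), 1L)]
        }, character(1))
      }
      x
    }
    if (is.null(entity_pool)) entity_pool <- unique(occ2$entity_name)
    if (length(entity_pool) > 1L) {
      occ2$entity_name <- flip_cat(occ2$entity_name, entity_pool)
    }
    occ2$health_class[!is.na(occ2$health_class)] <-
      flip_cat(occ2$health_class[!is.na(occ2$health_class)], health_levels())
    hit <- stats::runif(n) < flip
    occ2$child_targeted[hit] <- !occ2$child_targeted[hit]
    hit <- stats::runif(n) < flip
    occ2$sports_related[hit] <- !occ2$sports_related[hit]
    sized <- !is.na(occ2$size_class)
    occ2$size_class[sized] <- flip_cat(occ2$size_class[sized], size_levels())
  }
  audit2 <- site_audit(audit$site_id, occ2, audit$pricing,
                       audit$n_concessions, audit$n_sports_areas)
  list(rater_audit("rater_1", audit), rater_audit("rater_2", audit2))
}

#' Generate sponsorship and sales outcomes coupled to the scores
#'
#' Computes the FoodMATS score of every audit and draws outcomes from the
#' configured ground-truth models on the square-root scale:
#' \code{sqrt(food sponsorship) = alpha + beta * sqrt(score) + noise}
#' (floored at 0); total sponsorship adds a score-independent component
#' (attenuating its correlation with the score);
#' \code{sqrt(weekly Least-Healthy sales) = g0 + g_sports *
#' n_sports_areas + g_score * sqrt(score) + noise} per channel. Each
#' outcome is then masked missing with the configured probability.
#'
#' @param audits List of \code{site_audit} objects.
#' @param params A [generator_params()] list.
#' @param seed Integer RNG seed.
#' @param config A [scoring_config()] used to score the audits.
#' @return A [site_outcomes()] table with attribute \code{"truth"} holding
#'   the generating coefficients.
#' @export
generate_outcomes <- function(audits, params = generator_params(),
                              seed = 1L, config = scoring_config()) {
  set.seed(seed)
  scored <- score_sites(audits, config)
  n <- nrow(scored)
  ss <- sqrt(scored$foodmats_score)
  sq_spon <- pmax(0, params$spon_alpha + params$spon_beta * ss +
                    stats::rnorm(n, 0, params$spon_sd))
  food_spon <- sq_spon^2
  other_spon <- pmax(0, stats::rnorm(n, params$other_spon_mean,
                                     params$other_spon_sd))^2
  total_spon <- food_spon + other_spon
  sq_conc <- pmax(0, params$gamma0 +
                    params$gamma_sports * scored$n_sports_areas +
                    params$gamma_score * ss +
                    stats::rnorm(n, 0, params$sales_sd))
  sq_vend <- pmax(0, params$vend0 +
                    params$vend_sports * scored$n_sports_areas +
                    params$vend_score * ss +
                    stats::rnorm(n, 0, params$vend_sd))
  conc <- sq_conc^2
  vend <- sq_vend^2
  miss_spon <- stats::runif(n) < params$p_missing_sponsorship
  miss_conc <- stats::runif(n) < params$p_missing_concession
  miss_vend <- stats::runif(n) < params$p_missing_vending
  food_spon[miss_spon] <- NA
  total_spon[miss_spon] <- NA
  conc[miss_conc] <- NA
  vend[miss_vend] <- NA
  out <- site_outcomes(
    site_id = scored$site_id,
    foodmats_score = scored$foodmats_score,
    n_concessions = scored$n_concessions,
    n_sports_areas = scored$n_sports_areas,
    food_sponsorship = food_spon,
    total_sponsorship = total_spon,
    sales_least_concession = conc,
    sales_least_vending = vend
  )
  attr(out, "truth") <- list(
    spon_alpha = params$spon_alpha, spon_beta = params$spon_beta,
    gamma0 = params$gamma0, gamma_sports = params$gamma_sports,
    gamma_score = params$gamma_score,
    vend0 = params$vend0, vend_sports = params$vend_sports,
    vend_score = params$vend_score
  )
  out
}

#' Expected kappa of a flip-perturbed binary attribute
#'
#' Closed-form expectation for the generator's two-rater design on a
#' binary attribute: rater 1 records truth with marginal probability
#' \code{p}; rater 2 toggles each value independently with probability
#' \code{flip}. Observed agreement is \code{1 - flip}; chance agreement
#' follows from the two marginals.
#'
#' @param p Truth marginal probability of the positive value.
#' @param flip Toggle probability.
#' @return The expected kappa.
#' @export
expected_flip_kappa <- function(p, flip) {
  po <- 1 - flip
  p2 <- p * (1 - flip) + (1 - p) * flip
  pe <- p * p2 + (1 - p) * (1 - p2)
  (po - pe) / (1 - pe)
}
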