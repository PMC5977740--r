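## Site scoring: exposure (frequency + repetition) and power (content,
## design, execution).
##
## Per area a (food, sport, other):
##   E_a  = number of marketing occasions in a (triggered pricing
##          indicators count as Least-Healthy pseudo-occasions in food)
##   A_a  = E_a * (1 + w_content*(p_least + w_less_fraction*p_less)
##                   + w_child*p_child + w_sport*p_sport)
##          + w_size * sum of size points over occasions with a size
## (size points: small 0, medium 0.5, large 1; when every occasion in
## the area carries a size the size term equals E_a * w_size * mean_size,
## i.e. the familiar frequency-times-power product; accruing size points
## only from sized occasions keeps the score monotone under appending
## occasions even though size is excluded for some pricing and place
## occasions)
## Site score:
##   S = sum_a A_a + w_repetition * R
## where R counts distinct marketed entities (name, kind) recorded at
## least `repetition_threshold` (default 3) times site-wide.
##
## The published instrument's verbatim point values are not in the public
## record; this multiplicative frequency-times-power form is the package's
## documented default. It preserves the instrument's ordering semantics
## (score strictly increases with exposure, with each powerful
## characteristic, and with repetition) and every constant is
## configurable, so an alternative point scheme can be dropped in.

#' Scoring configuration
#'
#' All weights of the site scoring algorithm. Defaults give each power
#' dimension (content, child-targeting, sports theme, size) equal unit
#' weight on top of a unit exposure baseline, count Less Healthy content
#' at half the Least Healthy weight (the content scale is ordered
#' Most < Less < Least), and add 2 points per repeatedly marketed entity
#' at the instrument's repetition threshold of 3 recordings per site.
#'
#' @param w_content Weight of unhealthfulness content (default 1).
#' @param w_child Weight of the child-targeting flag proportion (default 1).
#' @param w_sport Weight of the sports-theme flag proportion (default 1).
#' @param w_size Weight of mean promotion size (default 1).
#' @param w_less_fraction Fraction of the content weight carried by a
#'   Less Healthy occasion relative to Least Healthy (default 0.5).
#' @param w_repetition Points per repeated entity (default 2).
#' @param repetition_threshold Recordings needed to count as repeated
#'   (default 3, as the instrument defines repetition; must be >= 2).
#' @return An object of class \code{scoring_config}.
#' @export
scoring_config <- function(w_content = 1, w_child = 1, w_sport = 1,
                           w_size = 1, w_less_fraction = 0.5,
                           w_repetition = 2, repetition_threshold = 3L) {
  w <- c(w_content = w_content, w_child = w_child, w_sport = w_sport,
         w_size = w_size, w_repetition = w_repetition)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("all weights must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(w_less_fraction) || w_less_fraction < 0 || w_less_fraction > 1) {
    stop("w_less_fraction must lie in [0, 1]", call. = FALSE)
  }
  repetition_threshold <- as.integer(repetition_threshold)
  if (is.na(repetition_threshold) || repetition_threshold < 2L) {
    stop("repetition_threshold must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(w_content = w_content, w_child = w_child, w_sport = w_sport,
         w_size = w_size, w_less_fraction = w_less_fraction,
         w_repetition = w_repetition,
         repetition_threshold = repetition_threshold),
    class = "scoring_config"
  )
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("FoodMATS scoring configuration\n")
  cat(sprintf("  power weights: content %g (less fraction %g), child %g, sport %g, size %g\n",
              x$w_content, x$w_less_fraction, x$w_child, x$w_sport, x$w_size))
  cat(sprintf("  repetition: %g points per entity recorded >= %d times\n",
              x$w_repetition, x$repetition_threshold))
  invisible(x)
}

# Effective occasions in an area: recorded occasions plus, in the food
# area, one Least-Healthy pseudo-occasion per triggered pricing indicator
# (no design flags, no size).
area_effective <- function(audit, area) {
  occ <- audit$occasions[audit$occasions$area == area, , drop = FALSE]
  out <- data.frame(
    health_class = occ$health_class,
    child_targeted = occ$child_targeted,
    sports_related = occ$sports_related,
    size_class = occ$size_class,
    stringsAsFactors = FALSE
  )
  if (area == "food" && nrow(audit$pricing)) {
    k <- sum(audit$pricing$triggered)
    if (k > 0L) {
      out <- rbind(out, data.frame(
        health_class = rep("least_healthy", k),
        child_targeted = rep(FALSE, k),
        sports_related = rep(FALSE, k),
        size_class = rep(NA_character_, k),
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Marketing-occasion frequency in an area
#'
#' Exposure component: the number of marketing occasions observed in the
#' area. Triggered pricing indicators are Least-Healthy marketing and are
#' counted in the food area.
#'
#' @param audit A \code{site_audit}.
#' @param area One of \code{area_levels()}.
#' @return Integer count.
#' @export
area_frequency <- function(audit, area = area_levels()) {
  area <- match.arg(area)
  nrow(area_effective(audit, area))
}

#' Power profile of an area
#'
#' The proportions of occasions in the area with each powerful
#' characteristic: Least/Less Healthy content, child-targeted design,
#' sports-related design, and the mean physical size on a 0-1 scale
#' (small = 0, medium = 0.5, large = 1, averaged over occasions that have
#' a size; size is excluded for some pricing and place occasions). An
#' empty area has an all-zero profile.
#'
#' @inheritParams area_frequency
#' @return A named list with p_least, p_less, p_child, p_sport, mean_size, n.
#' @export
power_profile <- function(audit, area = area_levels()) {
  area <- match.arg(area)
  eff <- area_effective(audit, area)
  n <- nrow(eff)
  if (n == 0L) {
    return(list(p_least = 0, p_less = 0, p_child = 0, p_sport = 0,
                mean_size = 0, n = 0L))
  }
  if (anyNA(eff$health_class)) {
    i <- which(is.na(eff$health_class))[1]
    stop(sprintf("area '%s': occasion %d has no healthfulness classification; classify all entities before scoring",
                 area, i), call. = FALSE)
  }
  size_num <- c(small = 0, medium = 0.5, large = 1)[eff$size_class]
  sized <- !is.na(size_num)
  list(
    p_least = mean(eff$health_class == "least_healthy"),
    p_less = mean(eff$health_class == "less_healthy"),
    p_child = mean(eff$child_targeted),
    p_sport = mean(eff$sports_related),
    mean_size = if (any(sized)) mean(size_num[sized]) else 0,
    n = n
  )
}

#' Repetition count
#'
#' The number of distinct marketed entities — identified by the
#' (entity name, kind) pair — recorded at least \code{threshold} times in
#' the whole site, across all areas.
#'
#' @param audit A \code{site_audit}.
#' @param threshold Integer >= 2; the instrument's definition uses 3
#'   ("recorded three or more times per facility").
#' @return Integer count of repeated entities.
#' @export
repetition_count <- function(audit, threshold = 3L) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 2L) {
    stop("threshold must be an integer >= 2", call. = FALSE)
  }
  occ <- audit$occasions
  if (nrow(occ) == 0L) return(0L)
  key <- paste(occ$entity_name, occ$entity_kind, sep = "\r")
  sum(table(key) >= threshold)
}

#' Score one area
#'
#' \code{A_a = E_a * (1 + w_content*(p_least + w_less_fraction*p_less) +
#' w_child*p_child + w_sport*p_sport) + w_size * S_a}, where \code{S_a}
#' is the sum of size points (small 0, medium 0.5, large 1) over the
#' area's occasions that carry a size. When every occasion has a size,
#' \code{S_a = E_a * mean_size} and the whole score is the
#' frequency-times-power product; when size is excluded for some
#' occasions, size points accrue only from the sized ones, which keeps
#' the score monotone under added exposure. An empty area scores 0.
#'
#' @inheritParams area_frequency
#' @param config A [scoring_config()].
#' @return Numeric area score.
#' @export
area_score <- function(audit, area = area_levels(), config = scoring_config()) {
  area <- match.arg(area)
  e <- area_frequency(audit, area)
  if (e == 0L) return(0)
  eff <- area_effective(audit, area)
  p <- power_profile(audit, area)
  size_num <- c(small = 0, medium = 0.5, large = 1)[eff$size_class]
  size_sum <- sum(size_num, na.rm = TRUE)
  e * (1 +
         config$w_content * (p$p_least + config$w_less_fraction * p$p_less) +
         config$w_child * p$p_child +
         config$w_sport * p$p_sport) +
    config$w_size * size_sum
}

#' Compute the FoodMATS score of a site
#'
#' Sums the three area scores and adds the repetition factor:
#' \code{S = A_food + A_sport + A_other + w_repetition * R}. Higher scores
#' represent settings with higher exposure to, and more powerful
#' (unhealthy, child-targeted, sports-related, large) food marketing.
#'
#' @param audit A \code{site_audit} whose occasions are all classified.
#' @param config A [scoring_config()].
#' @return An object of class \code{foodmats_score}: per-area frequencies,
#'   power profiles and scores, the repetition count, and the total.
#' @examples
#' occ <- marketing_occasions("s1", "food", 1, "Fizz Cola", "brand",
#'                            "least_healthy", TRUE, FALSE, "large")
#' foodmats_score(site_audit("s1", occ))
#' @export
foodmats_score <- function(audit, config = scoring_config()) {
  stopifnot(inherits(audit, "site_audit"))
  areas <- area_levels()
  freq <- vapply(areas, function(a) area_frequency(audit, a), integer(1))
  power <- lapply(areas, function(a) power_profile(audit, a))
  names(power) <- areas
  scores <- vapply(areas, function(a) area_score(audit, a, config), numeric(1))
  rep_n <- repetition_count(audit, config$repetition_threshold)
  structure(
    list(site_id = audit$site_id,
         frequency = freq,
         power = power,
         area_scores = scores,
         repetition_count = rep_n,
         total = sum(scores) + config$w_repetition * rep_n,
         config = config),
    class = "foodmats_score"
  )
}

#' @export
print.foodmats_score <- function(x, digits = 2, ...) {
  cat(sprintf("FoodMATS score for site '%s': %.*f points\n",
              x$site_id, digits, x$total))
  cat(sprintf("  areas (food/sport/other): E = %s; A = %s\n",
              paste(x$frequency, collapse = "/"),
              paste(formatC(x$area_scores, digits = digits, format = "f"),
                    collapse = "/")))
  cat(sprintf("  repeated entities (>= %d recordings): %d\n",
              x$config$repetition_threshold, x$repetition_count))
  invisible(x)
}

#' @export
summary.foodmats_score <- function(object, ...) {
  p <- object$power
  tab <- data.frame(
    area = area_levels(),
    frequency = unname(object$frequency),
    p_least = vapply(p, `[[`, numeric(1), "p_least"),
    p_less = vapply(p, `[[`, numeric(1), "p_less"),
    p_child = vapply(p, `[[`, numeric(1), "p_child"),
    p_sport = vapply(p, `[[`, numeric(1), "p_sport"),
    mean_size = vapply(p, `[[`, numeric(1), "mean_size"),
    area_score = unname(object$area_scores),
    row.names = NULL
  )
  structure(list(site_id = object$site_id, areas = tab,
                 repetition_count = object$repetition_count,
                 total = object$total),
            class = "summary.foodmats_score")
}

#' @export
print.summary.foodmats_score <- function(x, ...) {
  cat(sprintf("FoodMATS score breakdown, site '%s'\n", x$site_id))
  print(x$areas, row.names = FALSE, digits = 3)
  cat(sprintf("repetition count: %d; total: %.2f\n",
              x$repetition_count, x$total))
  invisible(x)
}

#' Score a list of site audits
#'
#' @param audits List of \code{site_audit} objects.
#' @param config A [scoring_config()].
#' @return A data.frame with one row per site: site_id, area scores,
#'   repetition count, total, and the size covariates.
#' @export
score_sites <- function(audits, config = scoring_config()) {
  rows <- lapply(audits, function(a) {
    s <- foodmats_score(a, config)
    data.frame(site_id = a$site_id,
               score_food = s$area_scores[["food"]],
               score_sport = s$area_scores[["sport"]],
               score_other = s$area_scores[["other"]],
               repetition_count = s$repetition_count,
               foodmats_score = s$total,
               n_concessions = a$n_concessions,
               n_sports_areas = a$n_sports_areas,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
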