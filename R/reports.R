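## Report writers tying the modules into the instrument's workflows:
## the combined score report over many sites and the two-rater
## reliability report with its six components:
##   (a) presence of food marketing by item            (percent, kappa)
##   (b) count of marketing occasions by area          (percent, ICC on
##       square-root transformed counts; single- and average-rater forms)
##   (c) product/brand/retailer marketed               (percent, kappa)
##   (d) child-targeted marketing                      (percent, kappa)
##   (e) sports-related marketing                      (percent, kappa)
##   (f) physical size                                 (percent, weighted kappa)
## Rows (c)-(f) are restricted to occasions identified by both raters,
## matched on the (area, item_id, entity_name) key; occasions sharing a
## key are paired in recording order up to the smaller count.

#' Score report over multiple audits
#'
#' Scores each audit, optionally writing per-site breakdown JSON files
#' and a combined CSV.
#'
#' @param audits A list of \code{site_audit} objects (or a single audit).
#' @param config A [scoring_config()].
#' @param out_dir Optional directory; when given, writes
#'   \code{scores.csv} plus one \code{<site_id>_breakdown.json} per site.
#' @return The combined score data.frame (invisibly when writing).
#' @export
score_report <- function(audits, config = scoring_config(), out_dir = NULL) {
  if (inherits(audits, "site_audit")) audits <- list(audits)
  for (a in audits) {
    viol <- validate_audit(a)
    if (length(viol)) {
      stop("audit '", a$site_id, "' failed validation:\n  ",
           paste(viol, collapse = "\n  "), call. = FALSE)
    }
  }
  combined <- score_sites(audits, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(combined, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    for (a in audits) {
      s <- foodmats_score(a, config)
      obj <- list(site_id = s$site_id, frequency = as.list(s$frequency),
                  power = s$power, area_scores = as.list(s$area_scores),
                  repetition_count = s$repetition_count, total = s$total)
      jsonlite::write_json(
        obj, file.path(out_dir, paste0(a$site_id, "_breakdown.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    return(invisible(combined))
  }
  combined
}

# Pair co-identified occasions of two audits on (area, item_id,
# entity_name); returns two index vectors into the occasion tables.
match_occasions <- function(occ1, occ2) {
  key1 <- paste(occ1$area, occ1$item_id, occ1$entity_name, sep = "\r")
  key2 <- paste(occ2$area, occ2$item_id, occ2$entity_name, sep = "\r")
  i1 <- integer(0); i2 <- integer(0)
  for (k in intersect(unique(key1), unique(key2))) {
    a <- which(key1 == k); b <- which(key2 == k)
    m <- min(length(a), length(b))
    i1 <- c(i1, a[seq_len(m)])
    i2 <- c(i2, b[seq_len(m)])
  }
  list(i1 = i1, i2 = i2)
}

#' Two-rater reliability report
#'
#' Builds the six-component inter-rater reliability table for one or more
#' rater pairs auditing the same site(s): per-item presence agreement,
#' per-area occasion-count ICC (on square-root transformed counts), and —
#' restricted to occasions both raters identified — agreement on the
#' entity marketed, the child-targeted flag, the sports-related flag and
#' the physical size. When the co-identified set is empty or degenerate
#' the affected rows carry NA statistics with a note.
#'
#' @param pairs A single two-element list of \code{rater_audit}s covering
#'   the same site, or a list of such pairs (one per site).
#' @param conf_level Confidence level for the intervals.
#' @param bands Kappa interpretation band set (see
#'   [interpret_agreement()]).
#' @return An object of class \code{foodmats_reliability}: a data.frame
#'   \code{table} (component, n, percent_agreement, statistic, estimate,
#'   ci_low, ci_high, p_value, band) plus any notes.
#' @export
reliability_report <- function(pairs, conf_level = 0.95,
                               bands = c("as_published", "conventional")) {
  bands <- match.arg(bands)
  if (length(pairs) == 2L && inherits(pairs[[1]], "rater_audit")) {
    pairs <- list(pairs)
  }
  for (p in pairs) {
    if (!inherits(p[[1]], "rater_audit") || !inherits(p[[2]], "rater_audit")) {
      stop("each pair must hold two rater_audit objects", call. = FALSE)
    }
    if (p[[1]]$audit$site_id != p[[2]]$audit$site_id) {
      stop("rater audits cover different sites: '",
           p[[1]]$audit$site_id, "' vs '", p[[2]]$audit$site_id, "'",
           call. = FALSE)
    }
  }
  notes <- character(0)

  # (a) presence by item, pooled over sites
  pres1 <- unlist(lapply(pairs, function(p) p[[1]]$item_presence))
  pres2 <- unlist(lapply(pairs, function(p) p[[2]]$item_presence))

  # (b) counts per area: subjects are site-by-area cells
  cnt <- do.call(rbind, lapply(pairs, function(p) {
    cbind(vapply(area_levels(), function(a)
      area_frequency(p[[1]]$audit, a), integer(1)),
      vapply(area_levels(), function(a)
        area_frequency(p[[2]]$audit, a), integer(1)))
  }))

  # (c)-(f): matched occasions pooled over sites
  m1 <- list(); m2 <- list()
  for (p in pairs) {
    mm <- match_occasions(p[[1]]$audit$occasions, p[[2]]$audit$occasions)
    m1[[length(m1) + 1L]] <- p[[1]]$audit$occasions[mm$i1, , drop = FALSE]
    m2[[length(m2) + 1L]] <- p[[2]]$audit$occasions[mm$i2, , drop = FALSE]
  }
  m1 <- do.call(rbind, m1)
  m2 <- do.call(rbind, m2)

  row_of <- function(component, n, pct, stat) {
    data.frame(component = component, n = n,
               percent_agreement = pct,
               statistic = if (is.null(stat)) NA_character_ else stat$statistic,
               estimate = if (is.null(stat)) NA_real_ else stat$estimate,
               ci_low = if (is.null(stat)) NA_real_ else stat$ci_low,
               ci_high = if (is.null(stat)) NA_real_ else stat$ci_high,
               p_value = if (is.null(stat)) NA_real_ else stat$p_value,
               band = if (is.null(stat)) NA_character_ else stat$band,
               stringsAsFactors = FALSE)
  }
  safe_kappa <- function(x, y, ordinal_levels = NULL) {
    tryCatch({
      if (is.null(ordinal_levels)) {
        withCallingHandlers(
          cohens_kappa(x, y, conf_level, bands),
          warning = function(w) invokeRestart("muffleWarning"))
      } else {
        withCallingHandlers(
          weighted_kappa(x, y, levels = ordinal_levels, conf_level = conf_level,
                         bands = bands),
          warning = function(w) invokeRestart("muffleWarning"))
      }
    }, error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NULL
    })
  }

  tab <- row_of("(a) presence of food marketing by item", length(pres1),
                percent_agreement(pres1, pres2),
                safe_kappa(pres1, pres2))
  icc1 <- tryCatch(icc_two_way_random(sqrt_transform(cnt), "single",
                                      conf_level),
                   error = function(e) {
                     notes <<- c(notes, conditionMessage(e)); NULL
                   })
  icck <- if (is.null(icc1)) NULL else
    icc_two_way_random(sqrt_transform(cnt), "average", conf_level)
  tab <- rbind(
    tab,
    row_of("(b) count of food marketing occasions by area (single rater)",
           nrow(cnt), percent_agreement(cnt[, 1], cnt[, 2]), icc1),
    row_of("(b) count of food marketing occasions by area (average of raters)",
           nrow(cnt), percent_agreement(cnt[, 1], cnt[, 2]), icck)
  )

  if (is.null(m1) || nrow(m1) == 0L) {
    notes <- c(notes,
               "no occasions identified by both raters; components (c)-(f) skipped")
    for (comp in c("(c) product marketed", "(d) child-targeted marketing",
                   "(e) sports-related marketing", "(f) physical size")) {
      tab <- rbind(tab, row_of(comp, 0L, NA_real_, NULL))
    }
  } else {
    tab <- rbind(
      tab,
      row_of("(c) product marketed", nrow(m1),
             percent_agreement(m1$entity_name, m2$entity_name),
             safe_kappa(m1$entity_name, m2$entity_name)),
      row_of("(d) child-targeted marketing", nrow(m1),
             percent_agreement(m1$child_targeted, m2$child_targeted),
             safe_kappa(m1$child_targeted, m2$child_targeted)),
      row_of("(e) sports-related marketing", nrow(m1),
             percent_agreement(m1$sports_related, m2$sports_related),
             safe_kappa(m1$sports_related, m2$sports_related))
    )
    sized <- !is.na(m1$size_class) & !is.na(m2$size_class)
    if (any(sized)) {
      tab <- rbind(tab, row_of(
        "(f) physical size", sum(sized),
        percent_agreement(m1$size_class[sized], m2$size_class[sized]),
        safe_kappa(m1$size_class[sized], m2$size_class[sized],
                   ordinal_levels = size_levels())))
    } else {
      notes <- c(notes, "no co-identified occasions carry a size; component (f) skipped")
      tab <- rbind(tab, row_of("(f) physical size", 0L, NA_real_, NULL))
    }
  }
  structure(list(table = tab, notes = notes,
                 n_sites = length(pairs)),
            class = "foodmats_reliability")
}

#' @export
print.foodmats_reliability <- function(x, digits = 3, ...) {
  cat(sprintf("FoodMATS inter-rater reliability (%d site pair%s)\n",
              x$n_sites, if (x$n_sites == 1L) "" else "s"))
  t <- x$table
  for (i in seq_len(nrow(t))) {
    pct <- if (is.na(t$percent_agreement[i])) "  --  " else
      sprintf("%5.1f%%", 100 * t$percent_agreement[i])
    st <- if (is.na(t$estimate[i])) "not estimable" else
      sprintf("%s = %.*f (95%% CI %.*f, %.*f) [%s]", t$statistic[i],
              digits, t$estimate[i], digits, t$ci_low[i], digits,
              t$ci_high[i], t$band[i])
    cat(sprintf("  %-62s n = %4d  %s  %s\n", t$component[i], t$n[i], pct, st))
  }
  for (nte in x$notes) cat("  note:", nte, "\n")
  invisible(x)
}

#' Export a reliability or validity report
#'
#' Writes the tabular part of a report as CSV (RFC 4180) or JSON.
#'
#' @param report A \code{foodmats_reliability} object.
#' @param path Destination path ending in .csv or .json.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "foodmats_reliability"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(table = report$table, notes = report$notes),
                         path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    utils::write.csv(report$table, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
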