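## End-to-end validity pipeline over a table of site outcomes, mirroring
## the instrument's validation workflow: square-root transforms, outlier
## truncation, sponsorship correlations (Pearson, Spearman, partial
## controlling for facility size), missing-data t-tests, a collinearity
## screen, and per-channel sequential regressions (Model 1 = facility
## size; Model 2 = facility size + score).

#' Assemble a site-outcomes table
#'
#' One row per site: the FoodMATS score, sponsorship dollars, weekly
#' Least-Healthy sales per channel, and the facility-size covariates.
#' \code{sales_least_total} is filled as concession + vending wherever
#' both are present and left missing otherwise.
#'
#' @param site_id,foodmats_score,n_concessions,n_sports_areas Required
#'   per-site vectors.
#' @param food_sponsorship,total_sponsorship,sales_least_concession,
#'   sales_least_vending Optional outcome vectors (NA = not provided).
#' @param sales_least_total Optional; computed from the channels when
#'   omitted.
#' @return A data.frame of class \code{site_outcomes}.
#' @export
site_outcomes <- function(site_id, foodmats_score, n_concessions,
                          n_sports_areas,
                          food_sponsorship = NA_real_,
                          total_sponsorship = NA_real_,
                          sales_least_concession = NA_real_,
                          sales_least_vending = NA_real_,
                          sales_least_total = NULL) {
  n <- length(site_id)
  df <- data.frame(
    site_id = as.character(site_id),
    foodmats_score = as.numeric(foodmats_score),
    food_sponsorship = rep_len(as.numeric(food_sponsorship), n),
    total_sponsorship = rep_len(as.numeric(total_sponsorship), n),
    sales_least_concession = rep_len(as.numeric(sales_least_concession), n),
    sales_least_vending = rep_len(as.numeric(sales_least_vending), n),
    n_concessions = as.integer(n_concessions),
    n_sports_areas = as.integer(n_sports_areas),
    stringsAsFactors = FALSE
  )
  if (is.null(sales_least_total)) {
    df$sales_least_total <- ifelse(
      !is.na(df$sales_least_concession) & !is.na(df$sales_least_vending),
      df$sales_least_concession + df$sales_least_vending, NA_real_)
  } else {
    df$sales_least_total <- rep_len(as.numeric(sales_least_total), n)
  }
  class(df) <- c("site_outcomes", "data.frame")
  df
}

#' Run the validity pipeline
#'
#' Reproduces the shape of the instrument's validity analysis on a
#' [site_outcomes()] table:
#' \enumerate{
#'   \item square-root transform of scores, sponsorship dollars and sales;
#'   \item truncation of outliers beyond \code{z} SD (on the transformed
#'     score and food sponsorship);
#'   \item Pearson, Spearman and partial correlations (controlling for
#'     the facility-size covariates) between score and food sponsorship,
#'     and the Pearson screen against total sponsorship;
#'   \item Welch t-tests comparing mean scores of sites with and without
#'     each outcome (the missing-data check);
#'   \item collinearity screen of score and size covariates against each
#'     sales outcome, dropping a flagged size covariate from Model 1;
#'   \item sequential regression per sales channel (concession, vending,
#'     total): Model 1 = facility size, Model 2 = + sqrt score.
#' }
#' Sites missing the variables of an analysis are excluded from that
#' analysis only, with counts logged; sections without usable data are
#' skipped with a log entry.
#'
#' @param outcomes A [site_outcomes()] table with at least \code{min_sites}
#'   rows.
#' @param alpha Two-sided significance level (default 0.05).
#' @param z Truncation threshold in SD units (default 3).
#' @param r_threshold Collinearity threshold (default 0.7).
#' @param min_sites Minimum number of sites (default 10).
#' @return An object of class \code{foodmats_validity} with components
#'   \code{sponsorship}, \code{regressions}, \code{missing_data},
#'   \code{collinearity}, \code{log}.
#' @export
run_validity_pipeline <- function(outcomes, alpha = 0.05, z = 3,
                                  r_threshold = 0.7, min_sites = 10L) {
  if (nrow(outcomes) < min_sites) {
    stop("validity pipeline needs at least ", min_sites, " sites (got ",
         nrow(outcomes), ")", call. = FALSE)
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  d <- as.data.frame(outcomes)
  d$sq_score <- sqrt_transform(d$foodmats_score)

  ## -- sponsorship correlations ----------------------------------------
  sponsorship <- NULL
  n_spon <- sum(!is.na(d$food_sponsorship))
  if (n_spon >= 6L) {
    sub <- d[!is.na(d$food_sponsorship), , drop = FALSE]
    sq_spon <- sqrt_transform(sub$food_sponsorship)
    tr_score <- truncate_outliers(sub$sq_score, z = z)
    tr_spon <- truncate_outliers(sq_spon, z = z)
    if (nrow(tr_score$log)) note("truncated %d score outlier(s)", nrow(tr_score$log))
    if (nrow(tr_spon$log)) note("truncated %d sponsorship outlier(s)", nrow(tr_spon$log))
    ctrl <- sub[c("n_concessions", "n_sports_areas")]
    food_cor <- correlations(tr_score$values, tr_spon$values, controls = ctrl)
    total_cor <- NULL
    if (sum(!is.na(d$total_sponsorship)) >= 6L) {
      tsub <- d[!is.na(d$total_sponsorship), , drop = FALSE]
      total_cor <- correlations(tsub$sq_score,
                                sqrt_transform(tsub$total_sponsorship))
      if (total_cor$pearson$p_value >= alpha) {
        note("total sponsorship not linearly associated with score (p = %.3f); no further total-sponsorship analysis",
             total_cor$pearson$p_value)
      }
    } else {
      note("total sponsorship: fewer than 6 sites provided data; section skipped")
    }
    sponsorship <- list(n = food_cor$n, food = food_cor, total = total_cor,
                        truncation = list(score = tr_score$log,
                                          sponsorship = tr_spon$log))
    note("sponsorship correlations on %d sites (%d excluded for missing data)",
         food_cor$n, nrow(d) - n_spon)
  } else {
    note("food sponsorship: fewer than 6 sites provided data; section skipped")
  }

  ## -- missing-data t-tests --------------------------------------------
  miss_vars <- c("food_sponsorship", "sales_least_concession",
                 "sales_least_vending", "sales_least_total")
  missing_data <- lapply(miss_vars, function(v) {
    have <- !is.na(d[[v]])
    if (sum(have) < 2L || sum(!have) < 2L) return(NULL)
    tt <- stats::t.test(d$foodmats_score[have], d$foodmats_score[!have])
    list(variable = v, n_present = sum(have), n_missing = sum(!have),
         mean_present = mean(d$foodmats_score[have]),
         mean_missing = mean(d$foodmats_score[!have]),
         p_value = tt$p.value)
  })
  names(missing_data) <- miss_vars
  missing_data <- Filter(Negate(is.null), missing_data)

  ## -- sales regressions -------------------------------------------------
  channels <- c(concession = "sales_least_concession",
                vending = "sales_least_vending",
                total = "sales_least_total")
  regressions <- list()
  collinearity <- list()
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!v %in% names(d)) {
      note("%s sales column absent; regression skipped", ch)
      next
    }
    sub <- d[!is.na(d[[v]]), , drop = FALSE]
    if (nrow(sub) < min_sites) {
      note("%s sales: only %d sites with data; regression skipped",
           ch, nrow(sub))
      next
    }
    y <- sqrt_transform(sub[[v]])
    size_vars <- c("n_concessions", "n_sports_areas")
    constant <- size_vars[vapply(size_vars,
                                 function(sv) stats::sd(sub[[sv]]) == 0,
                                 logical(1))]
    if (length(constant)) {
      note("%s sales: size covariate(s) %s constant in this subsample; dropped",
           ch, paste(constant, collapse = ", "))
      size_vars <- setdiff(size_vars, constant)
    }
    preds <- sub[c("sq_score", size_vars)]
    screen <- collinearity_screen(preds, y, r_threshold = r_threshold,
                                  alpha = alpha)
    collinearity[[ch]] <- screen
    dropped <- intersect(unique(screen$drop), size_vars)
    if (length(dropped)) {
      note("%s sales: dropped collinear size covariate(s) %s", ch,
           paste(dropped, collapse = ", "))
      size_vars <- setdiff(size_vars, dropped)
    }
    if ("sq_score" %in% unique(screen$drop)) {
      note("%s sales: score flagged collinear but retained (it is the variable under validation)",
           ch)
    }
    if (!length(size_vars)) {
      note("%s sales: all size covariates dropped; regression skipped", ch)
      next
    }
    regressions[[ch]] <- sequential_regression(
      y, block1 = sub[size_vars], block2 = sub["sq_score"])
    note("%s sales regression on %d sites (%d excluded for missing data)",
         ch, nrow(sub), nrow(d) - nrow(sub))
  }

  structure(list(sponsorship = sponsorship, regressions = regressions,
                 missing_data = missing_data, collinearity = collinearity,
                 alpha = alpha, n_sites = nrow(d), log = log),
            class = "foodmats_validity")
}

#' @export
print.foodmats_validity <- function(x, digits = 3, ...) {
  cat(sprintf("FoodMATS validity report (%d sites)\n", x$n_sites))
  if (!is.null(x$sponsorship)) {
    f <- x$sponsorship$food
    cat(sprintf("Food sponsorship (n = %d): r = %.*f (p = %s), rho = %.*f (p = %s), partial r = %.*f (p = %s)\n",
                f$n, digits, f$pearson$estimate,
                format.pval(f$pearson$p_value, digits = 3, eps = 1e-4),
                digits, f$spearman$estimate,
                format.pval(f$spearman$p_value, digits = 3, eps = 1e-4),
                digits, f$partial$estimate,
                format.pval(f$partial$p_value, digits = 3, eps = 1e-4)))
  }
  for (ch in names(x$regressions)) {
    m2 <- x$regressions[[ch]]$models$model2
    cat(sprintf("%s sales (n = %d): Model 2 R2 = %.*f, dR2 = %.*f, F(%d, %d) = %.3f, p = %s\n",
                ch, x$regressions[[ch]]$n, digits, m2$r_squared,
                digits, m2$delta_r_squared, m2$df_change[1],
                m2$df_change[2], m2$f_change,
                format.pval(m2$p_change, digits = 3, eps = 1e-4)))
  }
  if (length(x$log)) {
    cat("log:\n")
    for (l in x$log) cat("  -", l, "\n")
  }
  invisible(x)
}
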