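## Validity pipeline: preprocessing (weekly Least-Healthy sales, outlier
## truncation, square-root transforms), correlation analyses (Pearson,
## Spearman, partial), collinearity screening, and sequential (nested
## hierarchical) regression with R-squared-change F tests.

#' Weekly Least-Healthy sales from a two-week itemized sales table
#'
#' Classifies every sold item with the product rules, sums the dollars of
#' Least Healthy items per channel, and converts the two-week total to one
#' week. Rows whose item cannot be classified are reported and their
#' channel is flagged excluded (poorly itemized sales data cannot be
#' classified by healthfulness).
#'
#' @param sales Data.frame with columns \code{item}, \code{channel}
#'   ("concession" or "vending") and \code{dollars}, covering two weeks
#'   with no unusual day.
#' @param rules A \code{foodmats_rules} object.
#' @param period_weeks Length of the sales period in weeks (default 2).
#' @return A list: \code{weekly} (named vector of dollars/week per channel,
#'   NA for excluded channels), \code{excluded_channels},
#'   \code{unclassified} (the offending rows).
#' @export
weekly_least_healthy_sales <- function(sales, rules = default_rules(),
                                       period_weeks = 2) {
  need <- c("item", "channel", "dollars")
  if (!all(need %in% names(sales))) {
    stop("sales table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  channels <- c("concession", "vending")
  bad <- setdiff(unique(sales$channel), channels)
  if (length(bad)) {
    stop("unknown sales channel(s): ", paste(bad, collapse = ", "),
         "; expected concession or vending", call. = FALSE)
  }
  cls <- rep(NA_character_, nrow(sales))
  ok <- rep(TRUE, nrow(sales))
  for (i in seq_len(nrow(sales))) {
    cls[i] <- tryCatch(classify_product(sales$item[i], rules = rules),
                       foodmats_unclassified = function(e) {
                         ok[i] <<- FALSE
                         NA_character_
                       })
  }
  unclassified <- sales[!ok, , drop = FALSE]
  excluded <- unique(unclassified$channel)
  weekly <- vapply(channels, function(ch) {
    if (ch %in% excluded) return(NA_real_)
    rows <- sales$channel == ch
    if (!any(rows)) return(NA_real_)
    sum(sales$dollars[rows & cls == "least_healthy"], na.rm = TRUE) /
      period_weeks
  }, numeric(1))
  list(weekly = weekly, excluded_channels = excluded,
       unclassified = unclassified)
}

#' Truncate extreme outliers
#'
#' Any value beyond \code{mean +/- z * SD} (sample SD, computed on the
#' full vector including the outliers) is replaced by one point above (or
#' below) the most extreme value inside the threshold — i.e. the next
#' closest value below z standard deviations, plus one unit in the
#' offending direction. Applied once, as in the analysis it implements.
#'
#' @param values Numeric vector, n >= 3 (NA ignored for the threshold and
#'   passed through).
#' @param z SD multiplier (default 3).
#' @param unit The "one point" step on the variable's measured scale
#'   (default 1).
#' @return A list: \code{values} (truncated vector) and \code{log}
#'   (data.frame of index, original, replacement; zero rows if nothing
#'   was truncated).
#' @export
truncate_outliers <- function(values, z = 3, unit = 1) {
  if (sum(!is.na(values)) < 3L) {
    stop("truncation needs at least 3 non-missing values", call. = FALSE)
  }
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  out <- values
  log <- data.frame(index = integer(0), original = numeric(0),
                    replacement = numeric(0))
  if (!is.finite(s) || s == 0) {
    return(list(values = out, log = log))
  }
  hi_thr <- m + z * s
  lo_thr <- m - z * s
  hi <- which(!is.na(values) & values > hi_thr)
  lo <- which(!is.na(values) & values < lo_thr)
  if (length(hi)) {
    inliers <- values[!is.na(values) & values <= hi_thr]
    repl <- max(inliers) + unit
    log <- rbind(log, data.frame(index = hi, original = values[hi],
                                 replacement = repl))
    out[hi] <- repl
  }
  if (length(lo)) {
    inliers <- values[!is.na(values) & values >= lo_thr]
    repl <- min(inliers) - unit
    log <- rbind(log, data.frame(index = lo, original = values[lo],
                                 replacement = repl))
    out[lo] <- repl
  }
  list(values = out, log = log)
}

#' Pearson, Spearman and partial correlations
#'
#' Computes the Pearson product-moment and Spearman rank correlations of
#' \code{x} and \code{y}, and — when control covariates are supplied — the
#' partial Pearson correlation, obtained by residualizing both variables
#' on the controls and correlating the residuals; with an empty control
#' set the partial correlation equals the Pearson correlation. Two-sided
#' p-values throughout (the partial test on n - 2 - q degrees of freedom).
#'
#' @param x,y Equal-length numeric vectors.
#' @param controls Optional data.frame/matrix of control covariates.
#' @return A list with pearson, spearman and partial components
#'   (estimate, p_value) and n.
#' @export
correlations <- function(x, y, controls = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  q <- 0L
  if (!is.null(controls)) {
    controls <- as.data.frame(controls)
    if (nrow(controls) != length(x)) {
      stop("controls must have one row per observation", call. = FALSE)
    }
    keep <- keep & stats::complete.cases(controls)
    q <- ncol(controls)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L + q) {
    stop("need at least ", 4L + q, " complete observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  pear <- stats::cor.test(x, y, method = "pearson")
  spear <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  if (q > 0L) {
    cdat <- controls[keep, , drop = FALSE]
    rx <- stats::resid(stats::lm(x ~ ., data = cdat))
    ry <- stats::resid(stats::lm(y ~ ., data = cdat))
    r <- stats::cor(rx, ry)
    df <- n - 2L - q
    tval <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tval), df)
    partial <- list(estimate = r, p_value = p, df = df)
  } else {
    partial <- list(estimate = unname(pear$estimate),
                    p_value = pear$p.value, df = n - 2L)
  }
  list(
    pearson = list(estimate = unname(pear$estimate), p_value = pear$p.value),
    spearman = list(estimate = unname(spear$estimate), p_value = spear$p.value),
    partial = partial,
    n = n
  )
}

#' Sequential (hierarchical) regression with R-squared change
#'
#' Fits the nested ordinary-least-squares models \code{outcome ~ block1}
#' (Model 1) and \code{outcome ~ block1 + block2} (Model 2) and reports,
#' per model, standardized coefficients with confidence intervals,
#' R-squared, adjusted R-squared, the R-squared increment over the
#' previous model, and the F-change test
#' \code{F = (dR2/dk) / ((1 - R2_full) / (n - k_full - 1))} with its
#' p-value (Model 1 is tested against the intercept-only model).
#'
#' @param outcome Numeric response vector.
#' @param block1 Data.frame of Model-1 predictors (the controlling block).
#' @param block2 Data.frame of predictors added in Model 2.
#' @param conf_level Confidence level for the standardized-beta intervals.
#' @return An object of class \code{foodmats_seqreg}.
#' @export
sequential_regression <- function(outcome, block1, block2,
                                  conf_level = 0.95) {
  block1 <- as.data.frame(block1)
  block2 <- as.data.frame(block2)
  dat <- cbind(data.frame(.y = outcome), block1, block2)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k_full <- ncol(block1) + ncol(block2)
  if (n <= k_full + 1L) {
    stop("need more observations than predictors plus one (n = ", n,
         ", predictors = ", k_full, ")", call. = FALSE)
  }
  check_rank <- function(X, labels) {
    qrX <- qr(cbind(1, as.matrix(X)))
    if (qrX$rank < ncol(X) + 1L) {
      dropped <- labels[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
  }
  check_rank(dat[-1], names(dat)[-1])

  fit_block <- function(vars, prev_r2, prev_k) {
    f <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", vars),
                                               collapse = " + ")))
    fit <- stats::lm(f, data = dat)
    r2 <- summary(fit)$r.squared
    adj <- summary(fit)$adj.r.squared
    kk <- length(vars)
    dk <- kk - prev_k
    dr2 <- r2 - prev_r2
    fch <- if (r2 >= 1 - 1e-12) Inf else (dr2 / dk) / ((1 - r2) / (n - kk - 1))
    pch <- if (is.infinite(fch)) 0 else
      stats::pf(fch, dk, n - kk - 1, lower.tail = FALSE)
    # standardized coefficients: refit on z-scored variables
    zdat <- as.data.frame(scale(dat[c(".y", vars)]))
    zfit <- stats::lm(f, data = zdat)
    ci <- stats::confint(zfit, level = conf_level)
    coefs <- data.frame(
      predictor = vars,
      beta = unname(stats::coef(zfit)[-1]),
      ci_low = ci[-1, 1],
      ci_high = ci[-1, 2],
      p_value = summary(zfit)$coefficients[-1, 4],
      row.names = NULL
    )
    list(predictors = vars, coefficients = coefs, r_squared = r2,
         adj_r_squared = adj, delta_r_squared = dr2, f_change = fch,
         df_change = c(dk, n - kk - 1), p_change = pch, fit = fit)
  }
  m1 <- fit_block(names(block1), 0, 0L)
  m2 <- fit_block(c(names(block1), names(block2)), m1$r_squared,
                  length(names(block1)))
  structure(list(models = list(model1 = m1, model2 = m2), n = n),
            class = "foodmats_seqreg")
}

#' @export
print.foodmats_seqreg <- function(x, digits = 3, ...) {
  cat(sprintf("Sequential regression (n = %d)\n", x$n))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("%s: R2 = %.*f (adj %.*f), dR2 = %.*f, F(%d, %d) = %.3f, p = %s\n",
                nm, digits, m$r_squared, digits, m$adj_r_squared,
                digits, m$delta_r_squared, m$df_change[1], m$df_change[2],
                m$f_change,
                format.pval(m$p_change, digits = 3, eps = 1e-4)))
    co <- m$coefficients
    for (i in seq_len(nrow(co))) {
      cat(sprintf("    %s: beta = %.*f (%.*f, %.*f), p = %s\n",
                  co$predictor[i], digits, co$beta[i], digits, co$ci_low[i],
                  digits, co$ci_high[i],
                  format.pval(co$p_value[i], digits = 3, eps = 1e-4)))
    }
  }
  invisible(x)
}

#' Collinearity screen for regression predictors
#'
#' Flags predictor pairs whose absolute Pearson correlation exceeds the
#' threshold and, for each flagged pair, recommends dropping the member
#' that is not itself associated with the outcome (two-sided p >= alpha);
#' when both or neither member is associated, the member with the weaker
#' outcome association is recommended.
#'
#' @param predictors Data.frame of at least two numeric predictors.
#' @param outcome Numeric response vector.
#' @param r_threshold Absolute-correlation threshold (default 0.7).
#' @param alpha Outcome-association significance level (default 0.05).
#' @return A data.frame of flagged pairs (var1, var2, r, drop) with zero
#'   rows when no pair exceeds the threshold.
#' @export
collinearity_screen <- function(predictors, outcome, r_threshold = 0.7,
                                alpha = 0.05) {
  predictors <- as.data.frame(predictors)
  if (ncol(predictors) < 2L) stop("need at least 2 predictors", call. = FALSE)
  keep <- stats::complete.cases(predictors) & !is.na(outcome)
  predictors <- predictors[keep, , drop = FALSE]
  outcome <- outcome[keep]
  nms <- names(predictors)
  out <- data.frame(var1 = character(0), var2 = character(0),
                    r = numeric(0), drop = character(0))
  assoc_p <- vapply(nms, function(v) {
    if (stats::sd(predictors[[v]]) == 0) return(1)
    stats::cor.test(predictors[[v]], outcome)$p.value
  }, numeric(1))
  for (i in seq_len(length(nms) - 1L)) {
    for (j in seq(i + 1L, length(nms))) {
      r <- stats::cor(predictors[[i]], predictors[[j]])
      if (is.na(r) || abs(r) <= r_threshold) next
      pi_ <- assoc_p[nms[i]]; pj <- assoc_p[nms[j]]
      drop <- if (pi_ >= alpha && pj < alpha) nms[i]
      else if (pj >= alpha && pi_ < alpha) nms[j]
      else if (pi_ >= pj) nms[i] else nms[j]
      out <- rbind(out, data.frame(var1 = nms[i], var2 = nms[j], r = r,
                                   drop = drop))
    }
  }
  out
}
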