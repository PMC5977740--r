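## Inter-rater reliability statistics for the two-rater audit design:
## percent agreement, Cohen's kappa (unweighted and weighted), and the
## Shrout-Fleiss two-way random-effects intraclass correlation.
##
## Kappa: kappa = (p_o - p_e) / (1 - p_e), p_o the observed (weighted)
## agreement, p_e the chance agreement from the marginal products. The
## weighted form uses agreement weights v_ij in [0,1] with v_ii = 1;
## identity weights recover the unweighted statistic. The asymptotic
## variance is the Fleiss-Cohen-Everitt large-sample expression, which
## yields the familiar Wald 95% CI; the p-value tests kappa = 0 with the
## null-hypothesis variance (marginals fixed, independence cell
## probabilities).

new_agreement_result <- function(statistic, estimate, ci_low, ci_high, n,
                                 p_value = NA_real_, band = NA_character_,
                                 extra = list()) {
  structure(
    c(list(statistic = statistic, estimate = estimate,
           ci_low = ci_low, ci_high = ci_high, n = n,
           p_value = p_value, band = band), extra),
    class = "foodmats_agreement"
  )
}

#' @export
print.foodmats_agreement <- function(x, digits = 3, ...) {
  ci <- if (is.na(x$ci_low)) "" else
    sprintf(" (95%% CI %.*f, %.*f)", digits, x$ci_low, digits, x$ci_high)
  pv <- if (is.na(x$p_value)) "" else
    sprintf(", p %s", format.pval(x$p_value, digits = 3, eps = 1e-3))
  band <- if (is.na(x$band)) "" else sprintf(" [%s]", x$band)
  cat(sprintf("%s = %.*f%s%s, n = %d%s\n", x$statistic, digits, x$estimate,
              ci, pv, x$n, band))
  invisible(x)
}

#' Percent agreement between two raters
#'
#' The proportion of occasions of perfect agreement out of all possible
#' occasions.
#'
#' @param x,y Equal-length rating vectors (any atomic type).
#' @return Proportion in [0, 1].
#' @export
percent_agreement <- function(x, y) {
  if (length(x) != length(y)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  if (length(x) == 0L) stop("no ratings supplied", call. = FALSE)
  mean(x == y)
}

# Cross-tabulate two rating vectors over a common category set.
rating_table <- function(x, y, levels = NULL) {
  if (length(x) != length(y)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  if (length(x) == 0L) stop("no ratings supplied", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(c(as.character(x), as.character(y))))
  table(factor(as.character(x), levels = levels),
        factor(as.character(y), levels = levels))
}

# Core kappa computation on a square contingency table with agreement
# weight matrix V (v_ii = 1). Returns estimate, Wald CI, and a p-value
# for H0: kappa = 0.
kappa_from_table <- function(tab, V, conf_level = 0.95) {
  n <- sum(tab)
  k <- nrow(tab)
  P <- tab / n
  r <- rowSums(P)
  c_ <- colSums(P)
  po <- sum(V * P)
  pe <- sum(V * outer(r, c_))
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) {
      warning("degenerate table: chance agreement is 1 with perfect agreement; kappa reported as 1 by convention",
              call. = FALSE)
      return(list(estimate = 1, ci_low = 1, ci_high = 1, n = n,
                  p_value = NA_real_, po = po, pe = pe))
    }
    stop("kappa undefined: chance agreement equals 1 with imperfect agreement",
         call. = FALSE)
  }
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt asymptotic variance
  vbar_row <- as.vector(V %*% c_)     # vbar_i. = sum_j c_j V[i,j]
  vbar_col <- as.vector(r %*% V)      # vbar_.j = sum_i r_i V[i,j]
  M <- V - outer(vbar_row, rep(1, k)) * (1 - kap) -
    outer(rep(1, k), vbar_col) * (1 - kap)
  varhat <- (sum(P * M^2) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  varhat <- max(varhat, 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- kap - z * sqrt(varhat)
  ci_high <- min(1, kap + z * sqrt(varhat))
  # H0 variance: independence cell probabilities, kappa = 0
  M0 <- V - outer(vbar_row, rep(1, k)) - outer(rep(1, k), vbar_col)
  var0 <- (sum(outer(r, c_) * M0^2) - pe^2) / (n * (1 - pe)^2)
  p_value <- if (var0 > 0) {
    2 * stats::pnorm(-abs(kap / sqrt(var0)))
  } else NA_real_
  list(estimate = kap, ci_low = ci_low, ci_high = ci_high, n = n,
       p_value = p_value, po = po, pe = pe)
}

#' Cohen's kappa for nominal ratings
#'
#' Chance-corrected agreement for two raters on a nominal scale, with the
#' asymptotic 95% confidence interval and the printed interpretation band.
#' Perfect agreement on a table where chance agreement is also perfect
#' (a single observed category) returns 1 with a warning.
#'
#' @param x,y Equal-length rating vectors, or \code{x} may be a square
#'   contingency table (then \code{y} is ignored).
#' @param conf_level Confidence level (default 0.95).
#' @param bands Interpretation band set passed to [interpret_agreement()].
#' @return A \code{foodmats_agreement} with fields estimate, ci_low,
#'   ci_high, n, p_value, band, and the intermediates po and pe.
#' @examples
#' cohens_kappa(c("a", "a", "b", "b"), c("a", "a", "b", "b"))
#' @export
cohens_kappa <- function(x, y = NULL, conf_level = 0.95,
                         bands = c("as_published", "conventional")) {
  bands <- match.arg(bands)
  tab <- if (is.table(x) || is.matrix(x)) as.table(x) else rating_table(x, y)
  if (nrow(tab) != ncol(tab)) stop("contingency table must be square", call. = FALSE)
  V <- diag(nrow(tab))
  res <- kappa_from_table(tab, V, conf_level)
  new_agreement_result("kappa", res$estimate, res$ci_low, res$ci_high,
                       res$n, res$p_value,
                       interpret_agreement(res$estimate, "kappa", bands),
                       extra = list(po = res$po, pe = res$pe))
}

#' Weighted kappa for ordinal ratings
#'
#' Cohen's kappa with partial credit for near-misses on an ordered scale.
#' Linear disagreement weights (the default; conservative for short
#' ordered scales) or quadratic weights; identity (0/1) weights recover
#' the unweighted statistic exactly.
#'
#' @param x,y Equal-length ordinal rating vectors, or \code{x} a square
#'   table.
#' @param levels Explicit category ordering (required unless \code{x} is a
#'   table whose dimnames are already in order, or the vectors are
#'   factors).
#' @param scheme "linear", "quadratic" or "identity".
#' @inheritParams cohens_kappa
#' @return A \code{foodmats_agreement}.
#' @export
weighted_kappa <- function(x, y = NULL, levels = NULL,
                           scheme = c("linear", "quadratic", "identity"),
                           conf_level = 0.95,
                           bands = c("as_published", "conventional")) {
  scheme <- match.arg(scheme)
  bands <- match.arg(bands)
  if (is.table(x) || is.matrix(x)) {
    tab <- as.table(x)
  } else {
    if (is.null(levels)) {
      if (is.factor(x)) levels <- levels(x)
      else stop("ordinal ratings need an explicit category ordering (levels=)",
                call. = FALSE)
    }
    bad <- setdiff(unique(c(as.character(x), as.character(y))), levels)
    if (length(bad)) {
      stop("rating(s) outside the declared ordering: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tab <- rating_table(x, y, levels = levels)
  }
  if (nrow(tab) != ncol(tab)) stop("contingency table must be square", call. = FALSE)
  k <- nrow(tab)
  idx <- seq_len(k)
  D <- abs(outer(idx, idx, "-"))
  V <- switch(scheme,
              identity = diag(k) * 1,
              linear = if (k == 1) diag(1) else 1 - D / (k - 1),
              quadratic = if (k == 1) diag(1) else 1 - (D / (k - 1))^2)
  res <- kappa_from_table(tab, V, conf_level)
  new_agreement_result("weighted_kappa", res$estimate, res$ci_low,
                       res$ci_high, res$n, res$p_value,
                       interpret_agreement(res$estimate, "kappa", bands),
                       extra = list(po = res$po, pe = res$pe,
                                    scheme = scheme))
}

#' Two-way random-effects intraclass correlation
#'
#' Shrout-Fleiss ICC(2,1) (single rater) and ICC(2,k) (average of the k
#' raters) from a complete subjects-by-raters matrix, under the two-way
#' random absolute-agreement model, with F-distribution 95% confidence
#' bounds (McGraw-Wong) and the F test of no subject effect.
#'
#' @param mat Numeric matrix, subjects in rows (>= 2), raters in columns
#'   (>= 2), no missing cells.
#' @param form "single" for ICC(2,1) or "average" for ICC(2,k).
#' @param conf_level Confidence level (default 0.95).
#' @return A \code{foodmats_agreement} with the ANOVA mean squares in its
#'   extra fields.
#' @export
icc_two_way_random <- function(mat, form = c("single", "average"),
                               conf_level = 0.95) {
  form <- match.arg(form)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("ICC requires a complete matrix (no missing cells)",
                       call. = FALSE)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) {
    stop("ICC needs at least 2 subjects and 2 raters", call. = FALSE)
  }
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 || (ss_rows < 1e-300 && ss_tot < 1e-300)) {
    stop("ICC undefined: no between-subject variance", call. = FALSE)
  }
  denom_single <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom_single) < 1e-300) {
    stop("ICC undefined: zero variance", call. = FALSE)
  }
  icc1 <- (msr - mse) / denom_single
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  # McGraw-Wong confidence bounds for ICC(A,1)
  alpha <- 1 - conf_level
  if (mse > 0) {
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    p_value <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1),
                         lower.tail = FALSE)
  } else {
    l1 <- u1 <- icc1
    p_value <- 0
  }
  sb <- function(r) r * k / (1 + (k - 1) * r)   # Spearman-Brown step-up
  if (form == "single") {
    est <- icc1; lo <- l1; hi <- u1; label <- "icc_single"
  } else {
    est <- icck; lo <- sb(l1); hi <- sb(u1); label <- "icc_average"
  }
  # negative-variance-component pathologies can push the point estimate
  # outside [0, 1]; report it as computed but leave the band unlabelled
  band <- if (est <= 1) interpret_agreement(est, "icc") else NA_character_
  new_agreement_result(label, est, min(lo, est), min(max(hi, est), 1), n,
                       p_value, band,
                       extra = list(msr = msr, msc = msc, mse = mse,
                                    k_raters = k,
                                    icc_single = icc1, icc_average = icck))
}

#' Square-root transform
#'
#' Element-wise square root, used to improve the normality of count and
#' dollar variables before ICC, correlation and regression analysis.
#'
#' @param values Numeric vector of non-negative values (NA passed through).
#' @return Numeric vector.
#' @export
sqrt_transform <- function(values) {
  if (length(values) == 0L) return(numeric(0))
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) {
    stop("square-root transform requires non-negative values", call. = FALSE)
  }
  sqrt(values)
}

#' Interpretation bands for agreement statistics
#'
#' Kappa bands as published with the instrument: 0.0-0.2 "fair",
#' 0.21-0.40 "poor", 0.41-0.60 "moderate", 0.61-0.80 "good", 0.81-1.00
#' "very good". Note the first two labels are swapped relative to the
#' usual Landis-Koch convention; the published ordering is reproduced
#' verbatim by default and \code{bands = "conventional"} restores
#' poor-then-fair. ICC bands: < 0.40 "poor", 0.40-0.59 "fair",
#' 0.60-0.74 "good", 0.75-1.00 "excellent".
#'
#' @param value Statistic value (<= 1).
#' @param statistic "kappa" or "icc".
#' @param bands For kappa, "as_published" (default) or "conventional".
#' @return Band label (character).
#' @export
interpret_agreement <- function(value, statistic = c("kappa", "icc"),
                                bands = c("as_published", "conventional")) {
  statistic <- match.arg(statistic)
  bands <- match.arg(bands)
  if (is.na(value)) return(NA_character_)
  if (value > 1 + 1e-9) stop("agreement statistics cannot exceed 1", call. = FALSE)
  if (statistic == "icc") {
    if (value < 0.40) "poor"
    else if (value < 0.60) "fair"
    else if (value < 0.75) "good"
    else "excellent"
  } else {
    lab <- if (bands == "as_published") c("fair", "poor") else c("poor", "fair")
    if (value <= 0.20) lab[1]
    else if (value <= 0.40) lab[2]
    else if (value <= 0.60) "moderate"
    else if (value <= 0.80) "good"
    else "very good"
  }
}
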