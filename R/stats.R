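#' Stratified descriptive summary
#'
#' Mean, median, standard deviation and 25th/75th percentiles (linear
#' interpolation between order statistics) of a descriptor, per stratum and
#' pooled. Empty strata are omitted with a warning.
#'
#' @param values Numeric vector.
#' @param strata Factor or character vector of the same length (e.g. gender).
#' @param total_label Label used for the pooled row, default `"total"`.
#' @return Data.frame with columns `stratum`, `n`, `mean`, `median`, `sd`,
#'   `p25`, `p75`.
#' @export
stratified_summary <- function(values, strata = NULL, total_label = "total") {
  one <- function(x, lab) {
    x <- x[is.finite(x)]
    data.frame(stratum = lab, n = length(x), mean = mean(x),
               median = stats::median(x), sd = stats::sd(x),
               p25 = stats::quantile(x, 0.25, names = FALSE),
               p75 = stats::quantile(x, 0.75, names = FALSE))
  }
  rows <- list()
  if (!is.null(strata)) {
    for (lev in unique(as.character(strata))) {
      sel <- as.character(strata) == lev
      if (!any(is.finite(values[sel]))) {
        warning(sprintf("stratum '%s' is empty; omitted", lev))
        next
      }
      rows[[length(rows) + 1]] <- one(values[sel], lev)
    }
  }
  rows[[length(rows) + 1]] <- one(values, total_label)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intraclass correlation ICC(3,k) with 95% confidence interval
#'
#' Two-way mixed-effects, consistency, average-of-k-raters intraclass
#' correlation from the two-way ANOVA decomposition of an n-targets by
#' k-raters matrix: `ICC(3,k) = (MS_T - MS_E) / MS_T`, where `MS_T` is the
#' between-target mean square and `MS_E` the residual mean square after
#' removing target and rater effects. The confidence interval uses the exact
#' F-distribution bounds of Shrout and Fleiss. Being a consistency
#' coefficient, it is invariant under adding a per-rater constant and under
#' common rescaling.
#'
#' @param counts Numeric matrix, rows = targets (patches), columns = raters.
#'   At least 2 of each, no missing entries.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `icc`, `ci` (length-2), `ms_targets`, `ms_error`,
#'   `df1`, `df2`, `fvalue`.
#' @export
icc3k <- function(counts, conf_level = 0.95) {
  m <- as.matrix(counts)
  if (any(!is.finite(m))) stop("rater matrix must have no missing entries")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  gm <- mean(m)
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  ss_t <- k * sum((rm_ - gm)^2)
  ss_r <- n * sum((cm - gm)^2)
  ss_e <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ms_t <- ss_t / df1
  ms_e <- ss_e / df2
  if (ms_t <= 0) stop("undefined ICC: zero between-target variance")
  icc <- (ms_t - ms_e) / ms_t
  alpha <- 1 - conf_level
  if (ms_e == 0) {
    ci <- c(1, 1)
    fv <- Inf
  } else {
    fv <- ms_t / ms_e
    fl <- fv / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fv * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c(1 - 1 / fl, 1 - 1 / fu)
  }
  list(icc = icc, ci = ci, ms_targets = ms_t, ms_error = ms_e,
       df1 = df1, df2 = df2, fvalue = fv)
}

#' Normalized min-max range of repeated counts
#'
#' The range between the minimum and maximum of a patch's rater counts,
#' normalized by their mean: `(max - min) / mean`. Scale-invariant.
#'
#' @param counts Numeric vector of one patch's counts (one per rater).
#' @return Nonnegative scalar.
#' @export
normalized_range <- function(counts) {
  m <- mean(counts)
  if (!is.finite(m) || m == 0) stop("undefined metric: mean count is zero")
  (max(counts) - min(counts)) / m
}

#' Automatic-count-within-manual-range check
#'
#' Tests whether an automatic cell count, adjusted for the proportion of the
#' patch that was unmasked (i.e. projected to a full-patch count by dividing
#' by the unmasked fraction), falls within the closed interval spanned by the
#' minimum and maximum manual counts.
#'
#' @param auto_count Automatic count on the unmasked part of the patch.
#' @param manual_counts Numeric vector of the raters' manual counts.
#' @param unmasked_fraction Fraction of the patch area that was unmasked, in
#'   `(0, 1]`.
#' @return Logical.
#' @export
within_range_check <- function(auto_count, manual_counts,
                               unmasked_fraction = 1) {
  if (unmasked_fraction <= 0) stop("unmasked_fraction must be positive")
  adj <- auto_count / unmasked_fraction
  adj >= min(manual_counts) && adj <= max(manual_counts)
}

#' Pairwise Pearson correlation matrix with significance flags
#'
#' Pearson correlations over pairwise-complete observations for every pair of
#' columns, with two-sided p-values from the t-statistic under the null of
#' zero correlation. A flag marks p < 0.001 (the conventional asterisk);
#' Benjamini-Hochberg adjusted q-values are reported alongside, without
#' altering the flags.
#'
#' @param data Data.frame or matrix of numeric variables (>= 3 complete pairs
#'   per correlation).
#' @param flag_level Significance level for the flag, default 0.001.
#' @return List of matrices `r`, `p`, `n`, `q`, and logical `flag`; zero-
#'   variance pairs are reported as missing.
#' @export
pearson_matrix <- function(data, flag_level = 0.001) {
  m <- as.matrix(data)
  v <- ncol(m)
  nm <- colnames(m)
  r <- p <- q <- matrix(NA_real_, v, v, dimnames = list(nm, nm))
  nmat <- matrix(0L, v, v, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (j <= i) next
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3) next
      x <- m[ok, i]; y <- m[ok, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  up <- upper.tri(p)
  q[up] <- stats::p.adjust(p[up], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(p) <- 0
  diag(q) <- 0
  list(r = r, p = p, n = nmat, q = q, flag = p < flag_level)
}

#' Linear age trend of a morphometric descriptor
#'
#' Ordinary least squares of a per-eye descriptor (typically mean cell
#' density) on age. The sign of the slope is the quantity of interest.
#'
#' @param values Numeric vector, one per eye.
#' @param age Ages in years.
#' @param conf_level Level for the slope confidence interval, default 0.95.
#' @return List with `slope`, `intercept`, `r`, `p` (two-sided, slope = 0),
#'   `slope_ci`, and the fitted `lm` object as `fit`.
#' @export
age_trend <- function(values, age, conf_level = 0.95) {
  ok <- is.finite(values) & is.finite(age)
  if (sum(ok) < 3) stop("need at least 3 eyes")
  if (stats::sd(age[ok]) == 0) stop("degenerate age variance")
  fit <- stats::lm(values[ok] ~ age[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(sign(stats::coef(fit)[2]) * sqrt(sm$r.squared)),
       p = sm$coefficients[2, 4],
       slope_ci = unname(stats::confint(fit, level = conf_level)[2, ]),
       fit = fit)
}
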