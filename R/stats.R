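#' Ordinary least squares on a design matrix
#'
#' Thin, explicit OLS used by the group-comparison and
#' partial-correlation routines: coefficients via the QR factorization,
#' coefficient standard errors from the residual variance with
#' `df = n - p`.  Rank deficiency is an error that names the collinear
#' columns rather than silently dropping them.
#'
#' @param y numeric outcome vector.
#' @param x numeric design matrix (include the intercept column
#'   yourself if wanted).
#' @return List with `coefficients`, `se`, `residuals`, `fitted`, `df`,
#'   `sigma2` (residual variance) and `vcov`.
#' @export
fit_glm <- function(y, x) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) abort("rows of `x` must match length of `y`.")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]] %||%
      paste("column", qx$pivot[(qx$rank + 1):ncol(x)])
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(x %*% beta)
  res <- y - fitted
  df <- length(y) - ncol(x)
  if (df < 1) abort("no residual degrees of freedom (n <= p).")
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  vcov <- sigma2 * xtx_inv
  se <- sqrt(diag(vcov))
  names(se) <- names(beta)
  list(coefficients = beta, se = se, residuals = res, fitted = fitted,
       df = df, sigma2 = sigma2, vcov = vcov)
}

#' Cohen's d with n-weighted pooled standard deviation
#'
#' Effect size between two groups, `d = (mean2 - mean1) / S_c` with
#' `S_c = sqrt((n1 s1^2 + n2 s2^2) / (n1 + n2))`.  Note the pooling
#' weights are the raw group sizes (no n - 2 small-sample correction):
#' this is the convention the accompanying analyses use, implemented
#' exactly as stated.
#'
#' @param n1,n2 group sizes.
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations.
#' @return Numeric d; positive when group 2 exceeds group 1.
#' @examples
#' cohens_d(22, 1.43, 0.08, 18, 1.36, 0.14) # approx -0.63
#' @export
cohens_d <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 1, n2 >= 1, sd1 >= 0, sd2 >= 0)
  s_c <- sqrt((n1 * sd1^2 + n2 * sd2^2) / (n1 + n2))
  if (s_c == 0) abort("pooled SD is zero; Cohen's d is undefined.")
  (mean2 - mean1) / s_c
}

#' Magnitude category of an effect size
#'
#' `|d| <= 0.2` negligible, `0.2 < |d| <= 0.5` small, `0.5 < |d| <= 0.8`
#' medium, `|d| > 0.8` large.
#'
#' @param d numeric (vectorised), finite.
#' @return Character vector of categories.
#' @export
effect_size_category <- function(d) {
  if (any(!is.finite(d))) abort("`d` must be finite.")
  a <- abs(d)
  dplyr::case_when(
    a > 0.8 ~ "large",
    a > 0.5 ~ "medium",
    a > 0.2 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Family-wise error correction
#'
#' Bonferroni over `m` tests: `min(1, m * p)` per test.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m number of tests in the family (>= number of p-values).
#' @return Corrected p-values.
#' @export
fwe_correct <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  if (m < length(p)) abort("`m` must be at least the number of tests.")
  pmin(1, m * p)
}

# model covariates used throughout the ALPS analyses
alps_covariates <- c("sex", "age", "icv", "education",
                     "hypertension", "hyperlipidemia", "fazekas")

# numeric covariate matrix (binary factors 0/1-coded), no intercept
covariate_matrix <- function(data, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing covariate column(s): ", paste(miss, collapse = ", ")))
  }
  cols <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (is.factor(x)) {
      if (nlevels(x) != 2) abort(sprintf("factor covariate `%s` must be binary.", v))
      as.numeric(x == levels(x)[2])
    } else {
      as.numeric(x)
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  if (any(!complete.cases(m))) {
    abort("covariates contain missing values; listwise completeness is required.")
  }
  m
}

#' Covariate-adjusted group comparison of the ALPS index
#'
#' Fits one general linear model of the ALPS index on group (dummy
#' coded, NGM reference) plus the seven covariates over all subjects,
#' then tests each requested pairwise contrast with a t test on the
#' contrast estimate (`df = n - p`).  p-values are corrected family-wise
#' by Bonferroni over the three pairwise contrasts.  Cohen's d is
#' computed from the raw (unadjusted) group summaries via [cohens_d()],
#' with the first-named group as reference (`M1`).
#'
#' @param data data frame with the outcome, a `group` factor and the
#'   covariate columns.
#' @param outcome name of the outcome column (default `"alps"`).
#' @param covariates covariate column names (default the seven-model
#'   set: sex, age, icv, education, hypertension, hyperlipidemia,
#'   fazekas).
#' @param m_fwe family size for the correction (default the number of
#'   pairwise contrasts).
#' @return An object of class `alps_glm`; `tidy()` gives the per-pair
#'   table (estimate, t, raw and FWE-corrected p, Cohen's d and its
#'   category), `glance()` the model-level summary.
#' @export
alps_group_comparison <- function(data, outcome = "alps",
                                  covariates = alps_covariates,
                                  m_fwe = NULL) {
  stopifnot(outcome %in% names(data), "group" %in% names(data))
  grp <- factor(data$group, levels = alps_group_levels)
  grp <- droplevels(grp)
  lv <- levels(grp)
  if (length(lv) < 2) abort("need at least two groups.")
  counts <- table(grp)
  if (any(counts < 2)) {
    abort(sprintf("every group needs >= 2 subjects (got %s).",
                  paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  y <- as.numeric(data[[outcome]])
  cm <- covariate_matrix(data, covariates)
  dummies <- sapply(lv[-1], function(l) as.numeric(grp == l))
  x <- cbind(`(Intercept)` = 1, dummies, cm)
  fit <- fit_glm(y, x)

  pairs <- utils::combn(lv, 2, simplify = FALSE)
  contrast_vec <- function(a, b) {
    cv <- setNames(numeric(ncol(x)), colnames(x))
    if (a != lv[1]) cv[a] <- -1
    if (b != lv[1]) cv[b] <- 1
    cv
  }
  rows <- purrr::map_dfr(pairs, function(pr) {
    cv <- contrast_vec(pr[1], pr[2])
    est <- sum(cv * fit$coefficients)
    se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
    tstat <- est / se
    p <- 2 * pt(-abs(tstat), fit$df)
    i1 <- grp == pr[1]
    i2 <- grp == pr[2]
    d <- cohens_d(sum(i1), mean(y[i1]), sd(y[i1]),
                  sum(i2), mean(y[i2]), sd(y[i2]))
    tibble(pair = paste(pr[1], "vs.", pr[2]),
           estimate = est, se = se, statistic = tstat, df = fit$df,
           p.value = p, cohens_d = d,
           magnitude = effect_size_category(d))
  })
  m <- m_fwe %||% nrow(rows)
  rows$p.fwe <- fwe_correct(rows$p.value, m)
  rows <- rows[, c("pair", "estimate", "se", "statistic", "df",
                   "p.value", "p.fwe", "cohens_d", "magnitude")]
  structure(list(contrasts = rows, fit = fit, n = length(y),
                 groups = lv, outcome = outcome, covariates = covariates,
                 terms = colnames(x)),
            class = "alps_glm")
}

#' @export
print.alps_glm <- function(x, ...) {
  cat(sprintf("<alps_glm> %s ~ group + %d covariates, n = %d\n",
              x$outcome, length(x$covariates), x$n))
  print(as.data.frame(x$contrasts), digits = 3)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname alps_group_comparison
#' @param x an `alps_glm` object.
#' @param ... unused.
#' @export
tidy.alps_glm <- function(x, ...) x$contrasts

#' @rdname alps_group_comparison
#' @export
glance.alps_glm <- function(x, ...) {
  tss <- sum((x$fit$residuals + x$fit$fitted - mean(x$fit$fitted + x$fit$residuals))^2)
  rss <- sum(x$fit$residuals^2)
  tibble(n = x$n, df.residual = x$fit$df, sigma = sqrt(x$fit$sigma2),
         r.squared = 1 - rss / tss)
}

#' Single pairwise group contrast
#'
#' Convenience wrapper around [alps_group_comparison()] returning the
#' one requested pair.
#'
#' @inheritParams alps_group_comparison
#' @param pair character length 2, e.g. `c("Pre-DM", "T2DM")`.
#' @return One-row tibble (see [alps_group_comparison()]).
#' @export
group_contrast <- function(data, pair, outcome = "alps",
                           covariates = alps_covariates) {
  stopifnot(length(pair) == 2)
  cmp <- alps_group_comparison(data, outcome, covariates)
  lab <- paste(pair[1], "vs.", pair[2])
  lab_rev <- paste(pair[2], "vs.", pair[1])
  out <- cmp$contrasts[cmp$contrasts$pair %in% c(lab, lab_rev), ]
  if (nrow(out) == 0) abort(sprintf("pair %s not present in the data.", lab))
  out
}

#' GLM-based partial correlation
#'
#' Residualises both variables on the covariates (with intercept) and
#' correlates the residuals.  The p-value comes from
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - k - 2` for `k`
#' covariates, two-sided; this is algebraically identical to the t test
#' of the `x` coefficient in the GLM of `y` on `x` plus covariates.
#'
#' @param data data frame.
#' @param y,x column names of the two variables.
#' @param covariates covariate column names (may be empty, giving the
#'   plain Pearson correlation).
#' @return One-row tibble: `r`, `df`, `statistic`, `p.value`, `n`.
#' @export
partial_correlation <- function(data, y = "alps", x = "homa_ir",
                                covariates = alps_covariates) {
  yv <- as.numeric(data[[y]])
  xv <- as.numeric(data[[x]])
  k <- length(covariates)
  n <- length(yv)
  if (n <= k + 2) abort("need n > (number of covariates) + 2.")
  if (k > 0) {
    cm <- cbind(1, covariate_matrix(data, covariates))
    ry <- fit_glm(yv, cm)$residuals
    rx <- fit_glm(xv, cm)$residuals
  } else {
    ry <- yv - mean(yv)
    rx <- xv - mean(xv)
  }
  if (sd(ry) == 0 || sd(rx) == 0) {
    abort("zero-variance residuals; partial correlation is undefined.")
  }
  r <- cor(ry, rx)
  df <- n - k - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  tibble(r = r, df = df, statistic = tstat,
         p.value = 2 * pt(-abs(tstat), df), n = n)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column j on the remaining
#' columns (with intercept).  Perfectly collinear columns are reported
#' as `Inf` with `collinear = TRUE` rather than as an error, so the
#' screening table can show what went wrong.
#'
#' @param data data frame or matrix of covariates (binary factors are
#'   0/1-coded).
#' @param covariates column names when `data` is a data frame with more
#'   than the covariates.
#' @return Tibble with `term`, `vif`, `collinear`.
#' @export
compute_vif <- function(data, covariates = NULL) {
  m <- if (is.matrix(data)) {
    data
  } else {
    covariate_matrix(data, covariates %||% intersect(alps_covariates, names(data)))
  }
  if (ncol(m) < 2) abort("VIF needs at least two columns.")
  vifs <- vapply(seq_len(ncol(m)), function(j) {
    yj <- m[, j]
    xj <- cbind(1, m[, -j, drop = FALSE])
    qx <- qr(xj)
    res <- qr.resid(qx, yj)
    ssr <- sum(res^2)
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) return(Inf) # constant column
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = colnames(m) %||% paste0("x", seq_len(ncol(m))),
         vif = vifs, collinear = !is.finite(vifs))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (df = groups - 1); with two groups this is the rank-sum comparison
#' used for pairwise demographic-table p-values.  All-identical values
#' return H = 0, p = 1.
#'
#' @param data data frame.
#' @param value,group column names of the measurement and grouping.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `n`.
#' @export
kruskal_wallis <- function(data, value, group) {
  x <- as.numeric(data[[value]])
  g <- factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2 || length(x) < 3) {
    abort("need >= 2 groups and >= 3 observations in total.")
  }
  if (length(unique(x)) == 1) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p.value = 1,
                  n = length(x)))
  }
  kt <- kruskal.test(x, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value, n = length(x))
}

#' Fisher's exact test for small contingency tables
#'
#' Exact conditional test with fixed margins (hypergeometric for 2 x 2,
#' network enumeration otherwise); the two-sided p-value sums the
#' probabilities of all margin-consistent tables no more probable than
#' the observed one.
#'
#' @param table matrix of non-negative integer counts (2 x 2 or 2 x 3).
#' @return One-row tibble: `p.value`, `n`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("`table` must contain non-negative integer counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("contingency table has an empty margin.")
  }
  ft <- fisher.test(table)
  tibble(p.value = ft$p.value, n = sum(table))
}
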