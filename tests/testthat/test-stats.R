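test_that("fit_glm matches an independent pseudoinverse solution", {
  set.seed(21)
  n <- 50; p <- 5
  x <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(x) <- c("(Intercept)", paste0("x", 1:(p - 1)))
  y <- rnorm(n)
  fit <- fit_glm(y, x)
  sv <- svd(x)
  beta_pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u) %*% y
  expect_equal(unname(fit$coefficients), drop(beta_pinv), tolerance = 1e-8)
  # exact-fit and intercept-only identities
  y2 <- drop(x %*% c(1, 2, -1, 0.5, 3))
  expect_equal(max(abs(fit_glm(y2, x)$residuals)), 0, tolerance = 1e-10)
  expect_equal(unname(fit_glm(y, matrix(1, n))$coefficients), mean(y))
  # rank deficiency names the collinear column
  xx <- cbind(x, dup = x[, 2])
  expect_error(fit_glm(y, xx), "dup")
})

test_that("Cohen's d uses the n-weighted pooled SD exactly as printed", {
  expect_equal(cohens_d(22, 1.43, 0.08, 18, 1.36, 0.14), -0.63,
               tolerance = 0.01)
  expect_equal(cohens_d(10, 2, 1, 12, 2, 3), 0)
  expect_equal(cohens_d(15, 1, 0.4, 15, 1.4, 0.4), 1)
  expect_error(cohens_d(5, 1, 0, 5, 2, 0), "pooled SD")
})

test_that("Cohen's d is antisymmetric and affine-invariant", {
  set.seed(4)
  for (i in 1:25) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.1, 2); s2 <- runif(1, 0.1, 2)
    d <- cohens_d(n1, m1, s1, n2, m2, s2)
    expect_equal(cohens_d(n2, m2, s2, n1, m1, s1), -d, tolerance = 1e-12)
    shift <- rnorm(1)
    expect_equal(cohens_d(n1, m1 + shift, s1, n2, m2 + shift, s2), d,
                 tolerance = 1e-12)
    k <- runif(1, 0.5, 4)
    expect_equal(abs(cohens_d(n1, k * m1, k * s1, n2, k * m2, k * s2)),
                 abs(d), tolerance = 1e-12)
  }
})

test_that("effect sizes are categorised by the strict printed bounds", {
  expect_equal(effect_size_category(c(-1.32, -0.63, 0.2, 0.35, -0.5, 0.8, 0.81)),
               c("large", "medium", "negligible", "small", "small",
                 "medium", "large"))
  expect_error(effect_size_category(NA_real_), "finite")
})

test_that("Bonferroni correction caps at one and is monotone", {
  expect_equal(fwe_correct(0.5, 3), 1.0)
  expect_equal(fwe_correct(0, 7), 0)
  expect_equal(fwe_correct(0.01, 3), 0.03)
  expect_equal(fwe_correct(c(0.01, 0.2), 3), p.adjust(c(0.01, 0.2), "bonferroni", n = 3))
  p <- sort(runif(20))
  expect_true(all(diff(fwe_correct(p, 20)) >= 0))
  expect_true(all(fwe_correct(p, 25) >= fwe_correct(p, 20)))
  expect_error(fwe_correct(1.2, 3), "\\[0, 1\\]")
  expect_error(fwe_correct(c(0.1, 0.2), 1), "at least")
})

test_that("partial correlation equals the GLM t-statistic transform", {
  set.seed(63)
  coh <- generate_cohort(quick_config(master_seed = 63))$cohort
  pc <- partial_correlation(coh, "alps", "homa_ir")
  expect_equal(pc$df, nrow(coh) - 7 - 2)
  # GLM route: t statistic of homa_ir in alps ~ homa_ir + covariates
  cm <- cbind(1, covariate_matrix(coh, c("homa_ir", alps_covariates)))
  fit <- fit_glm(as.numeric(coh$alps), cm)
  tt <- fit$coefficients[2] / fit$se[2]
  expect_equal(pc$r, unname(sign(tt) * abs(tt) / sqrt(tt^2 + pc$df)),
               tolerance = 1e-8)
  expect_equal(pc$statistic, unname(tt), tolerance = 1e-8)
  # no covariates: collapses to Pearson
  pc0 <- partial_correlation(coh, "alps", "homa_ir", covariates = character())
  expect_equal(pc0$r, cor(coh$alps, coh$homa_ir), tolerance = 1e-12)
  # perfect dependence after adjustment
  coh$twin <- coh$alps
  expect_equal(partial_correlation(coh, "alps", "twin")$r, 1,
               tolerance = 1e-10)
})

test_that("VIF matches the R-squared definition and flags collinearity", {
  set.seed(8)
  x <- matrix(rnorm(200 * 4), 200)
  colnames(x) <- paste0("v", 1:4)
  q <- qr.Q(qr(scale(x, scale = FALSE))) # centered orthonormal columns
  colnames(q) <- colnames(x)
  expect_equal(compute_vif(q)$vif, rep(1, 4), tolerance = 1e-10)
  v <- compute_vif(x)
  skip_if_not_installed("car")
  df <- data.frame(y = rnorm(200), x)
  ref <- unname(car::vif(lm(y ~ v1 + v2 + v3 + v4, df)))
  expect_equal(v$vif, ref, tolerance = 1e-8)
  dup <- cbind(x, v5 = x[, 1])
  vd <- compute_vif(dup)
  expect_true(vd$collinear[vd$term %in% c("v1", "v5")][1])
  expect_true(is.infinite(vd$vif[1]))
})

test_that("default synthetic cohort covariates pass the VIF < 5 screen", {
  coh <- generate_cohort(cohort_config(master_seed = 14))$cohort
  v <- compute_vif(coh, alps_covariates)
  expect_true(all(v$vif < 5))
})

test_that("Kruskal-Wallis reproduces the hand-ranked oracle", {
  d <- data.frame(x = c(1, 2, 3, 4, 5, 6),
                  g = rep(c("a", "b"), each = 3))
  kw <- kruskal_wallis(d, "x", "g")
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-10)
  perm <- data.frame(x = c(5, 1, 3, 1, 5, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(perm, "x", "g")$statistic, 0, tolerance = 1e-12)
  same <- data.frame(x = rep(2, 6), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(same, "x", "g")$p.value, 1)
})

test_that("Kruskal-Wallis null p-values are approximately uniform", {
  set.seed(512)
  ps <- replicate(2000, {
    d <- data.frame(x = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
    kruskal_wallis(d, "x", "g")$p.value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.04)
})

test_that("Fisher's exact test matches exhaustive enumeration", {
  tab <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab)$p.value, 2 / 252, tolerance = 1e-10)
  expect_equal(fisher_enum_2x2(tab), 2 / 252, tolerance = 1e-10)
  same <- matrix(c(4, 6, 4, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact(same)$p.value, 1)
  set.seed(19)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 5), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher_exact(t2)$p.value, fisher_enum_2x2(t2),
                 tolerance = 1e-7)
  }
  for (i in 1:10) {
    t3 <- matrix(rpois(6, 4), 2)
    if (any(rowSums(t3) == 0) || any(colSums(t3) == 0)) next
    expect_equal(fisher_exact(t3)$p.value, fisher_enum_2x3(t3),
                 tolerance = 1e-6)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)),
               "margin")
})

test_that("adjusted group comparison has coherent contrasts and FWE", {
  coh <- generate_cohort(cohort_config(master_seed = 77))
  meas <- coh$cohort # true ALPS as outcome
  cmp <- alps_group_comparison(meas)
  td <- tidy(cmp)
  expect_equal(nrow(td), 3)
  expect_setequal(td$pair, c("NGM vs. Pre-DM", "NGM vs. T2DM",
                             "Pre-DM vs. T2DM"))
  expect_equal(td$p.fwe, pmin(1, 3 * td$p.value))
  expect_true(all(td$p.fwe >= td$p.value))
  # d sign matches the raw mean difference direction
  mns <- tapply(meas$alps, meas$group, mean)
  expect_equal(sign(td$cohens_d[td$pair == "NGM vs. T2DM"]),
               sign(mns["T2DM"] - mns["NGM"]), ignore_attr = TRUE)
  g1 <- glance(cmp)
  expect_true(g1$r.squared >= 0 && g1$r.squared <= 1)
  # single-pair helper agrees with the full table
  one <- group_contrast(meas, c("Pre-DM", "T2DM"))
  expect_equal(one$estimate, td$estimate[td$pair == "Pre-DM vs. T2DM"])
  expect_error(alps_group_comparison(meas[meas$group == "NGM", ]),
               "two groups")
})

test_that("demographic table covers both test families", {
  coh <- generate_cohort(cohort_config(master_seed = 31))$cohort
  dt <- demographic_table(coh)
  expect_true(all(c("sex", "age", "homa_ir", "alps") %in% dt$variable))
  pcols <- grep("^p ", names(dt), value = TRUE)
  expect_length(pcols, 3)
  expect_true(all(unlist(dt[pcols]) >= 0 & unlist(dt[pcols]) <= 1))
})
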