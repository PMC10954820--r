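test_that("OLS is exact on noiseless forward-model data", {
  sch <- test_scheme()
  set.seed(101)
  tensors <- t(replicate(100, random_pd_tensor()))
  fitted <- fit_tensors_via_volume(tensors, sch, noise_sigma = 0)
  rel <- abs(fitted - tensors) / pmax(abs(tensors), 1e-9)
  expect_lt(max(rel[abs(tensors) > 1e-9]), 1e-10)
})

test_that("flat signal fits to a zero tensor", {
  sch <- test_scheme()
  dwi <- array(1, dim = c(2, 2, 2, length(sch$bvals)))
  fit <- fit_tensor_ols(dwi, sch)
  expect_equal(max(abs(fit$d)), 0, tolerance = 1e-12)
  expect_equal(unique(as.vector(fit$log_s0)), 0, tolerance = 1e-12)
})

test_that("non-positive signals are clamped and counted", {
  sch <- test_scheme()
  dwi <- array(1, dim = c(1, 1, 1, length(sch$bvals)))
  dwi[1, 1, 1, 5] <- -0.2
  dwi[1, 1, 1, 9] <- 0
  expect_no_error(fit <- fit_tensor_ols(dwi, sch))
  expect_equal(fit$n_clamped, 2L)
  # all-zero voxels are dropped from the mask, not fitted
  dwi0 <- array(0, dim = c(2, 1, 1, length(sch$bvals)))
  dwi0[2, 1, 1, ] <- 1
  expect_message(fit0 <- fit_tensor_ols(dwi0, sch), "dropped 1")
  expect_equal(as.vector(fit0$mask), c(FALSE, TRUE))
})

test_that("tensor error decreases monotonically as noise vanishes", {
  sch <- test_scheme()
  set.seed(7)
  tensors <- t(replicate(60, random_pd_tensor()))
  err <- sapply(c(1e-2, 1e-3, 1e-4), function(sg) {
    fitted <- fit_tensors_via_volume(tensors, sch, noise_sigma = sg,
                                     seed = 11)
    diag_idx <- c(1, 4, 6)
    median(abs(fitted[, diag_idx] - tensors[, diag_idx]) /
             abs(tensors[, diag_idx]))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[1], 0.05) # 1% Rician noise: median diagonal error < 5%
})

test_that("closed-form eigenvalues match LAPACK on random tensors", {
  set.seed(33)
  tensors <- t(replicate(200, random_pd_tensor()))
  ours <- eig3_sym(tensors)
  ref <- t(apply(tensors, 1, function(v) {
    m <- matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3)
    eigen(m, symmetric = TRUE, only.values = TRUE)$values
  }))
  expect_equal(ours, ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("FA matches the eigenvalue-dispersion oracle", {
  mk_field <- function(t6) {
    d <- array(0, dim = c(1, 1, 1, 6))
    d[1, 1, 1, ] <- t6
    structure(list(d = d, s0 = array(1, c(1, 1, 1)),
                   mask = array(TRUE, c(1, 1, 1)), voxel_size = 1.8,
                   n_clamped = 0L), class = "tensor_field")
  }
  fa_of <- function(t6) compute_scalar_maps(mk_field(t6))$fa[1, 1, 1]
  # isotropic: zero dispersion
  expect_equal(fa_of(c(1e-3, 0, 0, 1e-3, 0, 1e-3)), 0)
  # prolate tensor against an independent eigen()-based computation
  t6 <- c(1.7e-3, 0, 0, 0.3e-3, 0, 0.3e-3)
  lam <- eigen(diag(c(1.7e-3, 0.3e-3, 0.3e-3)), symmetric = TRUE)$values
  fa_ref <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(fa_of(t6), fa_ref, tolerance = 1e-12)
  expect_equal(fa_of(t6), 0.7994, tolerance = 1e-3)
  # rank-1: maximal anisotropy
  expect_equal(fa_of(c(1e-3, 0, 0, 0, 0, 0)), 1, tolerance = 1e-8)
})

test_that("FA is invariant under rotation and scaling, and bounded", {
  set.seed(91)
  for (i in 1:25) {
    t6 <- random_pd_tensor()
    m <- matrix(c(t6[1], t6[2], t6[3], t6[2], t6[4], t6[5],
                  t6[3], t6[5], t6[6]), 3)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    mr <- q %*% m %*% t(q)
    tr6 <- c(mr[1, 1], mr[1, 2], mr[1, 3], mr[2, 2], mr[2, 3], mr[3, 3])
    fa <- function(v) {
      ev <- pmax(eig3_sym(matrix(v, 1)), 0)
      sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
    }
    expect_equal(fa(t6), fa(tr6), tolerance = 1e-8)
    expect_equal(fa(t6), fa(t6 * 3.7), tolerance = 1e-12)
    expect_true(fa(t6) >= 0 && fa(t6) <= 1)
  }
})

test_that("color-FA encodes the principal direction with unit-bounded channels", {
  geom <- test_geometry()
  tf <- build_tensor_field(geom, uniform_truth(1.2))
  maps <- compute_scalar_maps(tf, color = TRUE)
  expect_true(all(maps$color_fa >= 0 & maps$color_fa <= 1))
  # projection band: fibers along z -> blue channel dominates
  pv <- geom$labels == alps_region_codes[["projection_left"]]
  blue <- maps$color_fa[, , , 3][pv]
  red <- maps$color_fa[, , , 1][pv]
  expect_true(all(blue > red))
  # association band: fibers along y -> green dominates
  av <- geom$labels == alps_region_codes[["association_left"]]
  expect_true(all(maps$color_fa[, , , 2][av] > maps$color_fa[, , , 1][av]))
})
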