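# shared fixtures: a desk-scale phantom and acquisition reused across files
test_geometry <- function(dim = 44) phantom_geometry(dim = dim, voxel_size = 1.8)
test_scheme <- function() make_scheme(n_directions = 64, bvalue = 1000)

uniform_truth <- function(alps = 1.5) {
  c(dxx_proj = alps * 1e-3, dxx_assoc = alps * 1e-3,
    dyy_proj = 1e-3, dzz_assoc = 1e-3)
}

# random symmetric positive-definite tensor with diffusivity-scale
# eigenvalues, as (xx, xy, xz, yy, yz, zz)
random_pd_tensor <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  lam <- sort(runif(3, 0.2e-3, 2.5e-3), decreasing = TRUE)
  d <- q %*% diag(lam) %*% t(q)
  c(d[1, 1], d[1, 2], d[1, 3], d[2, 2], d[2, 3], d[3, 3])
}

# noiseless Stejskal-Tanner signals for one tensor under a scheme
forward_signal <- function(tensor6, scheme, s0 = 1) {
  d <- matrix(c(tensor6[1], tensor6[2], tensor6[3],
                tensor6[2], tensor6[4], tensor6[5],
                tensor6[3], tensor6[5], tensor6[6]), 3, 3)
  sapply(seq_along(scheme$bvals), function(i) {
    g <- scheme$bvecs[i, ]
    s0 * exp(-scheme$bvals[i] * drop(t(g) %*% d %*% g))
  })
}

# fit a set of single tensors by packing them into a 1-voxel-per-tensor
# volume; returns an n x 6 matrix of fitted elements
fit_tensors_via_volume <- function(tensors, scheme, noise_sigma = 0,
                                   seed = 1) {
  n <- nrow(tensors)
  d <- array(0, dim = c(n, 1, 1, 6))
  for (el in 1:6) d[, 1, 1, el] <- tensors[, el]
  tf <- structure(list(d = d, s0 = array(1, dim = c(n, 1, 1)),
                       mask = array(TRUE, dim = c(n, 1, 1)),
                       voxel_size = 1.8, n_clamped = 0L),
                  class = "tensor_field")
  dwi <- simulate_dwi(tf, scheme, noise_sigma = noise_sigma, seed = seed)
  fit <- fit_tensor_ols(dwi, scheme)
  matrix(fit$d, nrow = n, ncol = 6)
}

# exhaustive Fisher oracle: enumerate all tables with the observed
# margins, sum probabilities <= observed (two-sided definition)
fisher_enum_2x2 <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(a) {
    dhyper(a, r[1], r[2], cs[1])
  }
  p_obs <- prob(tab[1, 1])
  amin <- max(0, cs[1] - r[2]); amax <- min(r[1], cs[1])
  ps <- sapply(amin:amax, prob)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

fisher_enum_2x3 <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logp <- function(t1) {
    # multivariate hypergeometric with fixed margins
    sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(c(t1, cs - t1)))
  }
  p_obs <- exp(logp(tab[1, ]))
  total <- 0
  for (a in 0:min(r[1], cs[1])) {
    for (b in 0:min(r[1] - a, cs[2])) {
      cc <- r[1] - a - b
      if (cc < 0 || cc > cs[3]) next
      t1 <- c(a, b, cc)
      if (any(cs - t1 < 0)) next
      p <- exp(logp(t1))
      if (p <= p_obs * (1 + 1e-7)) total <- total + p
    }
  }
  total
}

# cohort config for quick statistical tests (no imaging)
quick_config <- function(...) {
  cohort_config(group_sizes = c(0L, 22L, 18L), ...)
}
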