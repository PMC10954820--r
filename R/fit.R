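#' Log-linear design matrix for diffusion tensor estimation
#'
#' One row per volume: `[-b gx^2, -2b gx gy, -2b gx gz, -b gy^2,
#' -2b gy gz, -b gz^2, 1]`, so that `row %*% c(Dxx, Dxy, Dxz, Dyy, Dyz,
#' Dzz, log S0)` equals the log of the noiseless signal.  Column order
#' matches the tensor element storage order, with log-S0 last.
#'
#' @param scheme an `alps_scheme`.
#' @return An n_volumes x 7 matrix.
#' @export
build_design_matrix <- function(scheme) {
  validate_scheme(scheme)
  g <- scheme$bvecs
  b <- scheme$bvals
  x <- cbind(
    -b * g[, 1]^2, -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
    -b * g[, 2]^2, -2 * b * g[, 2] * g[, 3], -b * g[, 3]^2,
    1
  )
  colnames(x) <- c("dxx", "dxy", "dxz", "dyy", "dyz", "dzz", "log_s0")
  if (qr(x)$rank < 7) {
    abort("acquisition scheme gives a rank-deficient tensor design (need >= 6 independent directions).")
  }
  x
}

#' Ordinary-least-squares diffusion tensor fit
#'
#' Fits the log-linearised tensor model voxelwise by OLS: per masked
#' voxel, regress log signal on [build_design_matrix()].  Non-positive
#' signals (possible under magnitude noise) are clamped to
#' `signal_floor` times the voxel's b = 0 signal before the log; the
#' number of clamped samples is recorded on the result.  Voxels whose
#' b = 0 signal is not positive are dropped from the mask.
#'
#' @param dwi 4-D array (nx, ny, nz, n_volumes).
#' @param scheme matching `alps_scheme`.
#' @param mask logical 3-D array; default all voxels.
#' @param signal_floor clamping floor as a fraction of the voxel b0.
#' @return A `tensor_field` with fitted elements, `log_s0` map, the
#'   (possibly reduced) mask, and `n_clamped`.
#' @export
fit_tensor_ols <- function(dwi, scheme, mask = NULL, signal_floor = 1e-6) {
  validate_scheme(scheme)
  dm <- dim(dwi)
  if (length(dm) != 4 || dm[4] != length(scheme$bvals)) {
    abort("`dwi` must be 4-D with one volume per scheme entry.")
  }
  if (is.null(mask)) mask <- array(TRUE, dim = dm[1:3])
  stopifnot(identical(dim(mask), dm[1:3]))
  x <- build_design_matrix(scheme)
  nvox <- prod(dm[1:3])
  sig <- matrix(dwi, nrow = nvox, ncol = dm[4])
  b0 <- rowMeans(sig[, scheme$bvals == 0, drop = FALSE])

  keep <- as.vector(mask) & b0 > 0
  n_dropped <- sum(mask) - sum(keep)
  if (n_dropped > 0) {
    message(sprintf("fit_tensor_ols: dropped %d voxel(s) with non-positive b0 signal.", n_dropped))
  }
  s <- sig[keep, , drop = FALSE]
  floor_mat <- signal_floor * b0[keep]
  clamped <- s < floor_mat # recycles floor per row (column-major)
  n_clamped <- sum(clamped)
  if (n_clamped > 0) s[clamped] <- rep(floor_mat, ncol(s))[clamped]

  beta <- qr.coef(qr(x), t(log(s))) # 7 x n_kept

  d <- array(0, dim = c(dm[1:3], 6))
  for (el in 1:6) {
    plane <- numeric(nvox)
    plane[keep] <- beta[el, ]
    d[, , , el] <- plane
  }
  ls0 <- numeric(nvox)
  ls0[keep] <- beta[7, ]
  out <- new_tensor_field(d, s0 = array(exp(ls0) * keep, dim = dm[1:3]),
                          mask = array(keep, dim = dm[1:3]),
                          voxel_size = NA_real_,
                          n_clamped = n_clamped)
  out$log_s0 <- array(ls0, dim = dm[1:3])
  out
}

# Closed-form eigenvalues of symmetric 3x3 tensors, vectorised over
# voxels (trigonometric solution of the characteristic cubic).
# `dmat`: n x 6 in order (xx, xy, xz, yy, yz, zz).  Returns n x 3,
# eigenvalues in decreasing order.
eig3_sym <- function(dmat) {
  a11 <- dmat[, 1]; a12 <- dmat[, 2]; a13 <- dmat[, 3]
  a22 <- dmat[, 4]; a23 <- dmat[, 5]; a33 <- dmat[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  # det(A - qI) / (2 p^3), guarded for the isotropic case p ~ 0
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detb <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detb / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  cbind(l1, l2, l3)
}

# Principal eigenvector per voxel for given leading eigenvalue, via the
# largest cross product of rows of (A - l1 I); vectorised.
principal_eigvec <- function(dmat, l1) {
  a11 <- dmat[, 1] - l1; a12 <- dmat[, 2]; a13 <- dmat[, 3]
  a22 <- dmat[, 4] - l1; a23 <- dmat[, 5]; a33 <- dmat[, 6] - l1
  cr <- function(u1, u2, u3, v1, v2, v3) {
    cbind(u2 * v3 - u3 * v2, u3 * v1 - u1 * v3, u1 * v2 - u2 * v1)
  }
  c12 <- cr(a11, a12, a13, a12, a22, a23)
  c13 <- cr(a11, a12, a13, a13, a23, a33)
  c23 <- cr(a12, a22, a23, a13, a23, a33)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  best <- max.col(cbind(n12, n13, n23), ties.method = "first")
  v <- c12
  v[best == 2, ] <- c13[best == 2, , drop = FALSE]
  v[best == 3, ] <- c23[best == 3, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  degen <- nrm < .Machine$double.eps # isotropic voxel: direction undefined
  v[degen, ] <- rep(c(1, 0, 0), each = sum(degen))
  nrm[degen] <- 1
  v / nrm
}

#' Scalar maps from a fitted tensor field
#'
#' Derives the axis diffusivity maps Dxx, Dyy, Dzz (tensor diagonal),
#' fractional anisotropy, and optionally the direction-encoded
#' (color-coded) FA map with RGB = |principal eigenvector| * FA.
#' Negative eigenvalues (possible after a noisy OLS fit) are clamped to
#' zero before FA so FA stays within `[0, 1]`.
#'
#' @param tensors a `tensor_field`.
#' @param color also compute the color-FA map (slower).
#' @return A `scalar_maps` object: list of 3-D arrays `dxx`, `dyy`,
#'   `dzz`, `fa`, the `mask`, and, if requested, a 4-D `color_fa`
#'   (nx, ny, nz, 3).
#' @export
compute_scalar_maps <- function(tensors, color = FALSE) {
  stopifnot(inherits(tensors, "tensor_field"))
  dm <- dim(tensors$d)[1:3]
  nvox <- prod(dm)
  dmat <- matrix(tensors$d, nrow = nvox, ncol = 6)
  ev <- eig3_sym(dmat)
  ev_c <- pmax(ev, 0)
  mbar <- rowMeans(ev_c)
  num <- rowSums((ev_c - mbar)^2)
  den <- rowSums(ev_c^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa[!as.vector(tensors$mask)] <- 0
  out <- list(
    dxx = array(dmat[, 1], dim = dm),
    dyy = array(dmat[, 4], dim = dm),
    dzz = array(dmat[, 6], dim = dm),
    fa = array(fa, dim = dm),
    mask = tensors$mask,
    voxel_size = tensors$voxel_size
  )
  if (color) {
    v <- principal_eigvec(dmat, ev[, 1])
    out$color_fa <- array(abs(v) * fa, dim = c(dm, 3))
  }
  structure(out, class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat(sprintf("<scalar_maps> %s voxels; FA range [%.3f, %.3f] in mask\n",
              paste(dim(x$fa), collapse = "x"),
              min(x$fa[x$mask]), max(x$fa[x$mask])))
  invisible(x)
}
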