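test_that("sphere voxelization matches brute-force center enumeration", {
  dim <- c(21, 21, 21)
  vs <- 1.8
  center <- (c(10, 10, 10)) * vs # a voxel center
  m <- voxelize_roi(center, 5.4, dim, vs)
  # brute force: every voxel center within 2.7 mm
  cnt <- 0
  for (i in 1:21) for (j in 1:21) for (k in 1:21) {
    d <- sqrt(sum((c(i - 1, j - 1, k - 1) * vs - center)^2))
    inside <- d <= 2.7
    cnt <- cnt + inside
    expect_equal(m[i, j, k], inside)
  }
  expect_equal(sum(m), 19) # quasi-sphere of 19 voxels at this grid ratio
  # sub-voxel diameter keeps only the central voxel
  expect_equal(sum(voxelize_roi(center, 1.0, dim, vs)), 1)
  expect_error(voxelize_roi(c(-50, 0, 0), 5.4, dim, vs), "outside")
  expect_error(suppressWarnings(voxelize_roi(c(0.9, 0.9, 0.9) * vs, 0.1, dim, vs)),
               "empty")
})

test_that("ROI means are plain voxel averages with mask exclusion", {
  geom <- test_geometry()
  dm <- geom$dim
  const_maps <- structure(list(
    dxx = array(3e-3, dm), dyy = array(2e-3, dm), dzz = array(1e-3, dm),
    fa = array(0.5, dm), mask = array(TRUE, dm),
    voxel_size = geom$voxel_size
  ), class = "scalar_maps")
  ex <- extract_roi_diffusivities(const_maps, default_roi_set(geom))
  expect_equal(ex$dxx_proj, rep(3e-3, 2))
  expect_equal(ex$dyy_proj, rep(2e-3, 2))
  expect_equal(ex$dzz_assoc, rep(1e-3, 2))
  # linear gradient along x: symmetric sphere -> mean equals center value
  co <- (seq_len(dm[1]) - 1) * geom$voxel_size
  grad <- array(rep(1e-3 + 1e-5 * co, prod(dm[2:3])), dim = dm)
  gm <- const_maps
  gm$dxx <- grad
  exg <- extract_roi_diffusivities(gm, default_roi_set(geom))
  centers <- default_roi_set(geom)
  ctr_val <- function(region, hemi) {
    r <- centers[centers$region == region & centers$hemisphere == hemi, ]
    1e-3 + 1e-5 * r$x
  }
  expect_equal(exg$dxx_proj[1], ctr_val("projection", "left"), tolerance = 1e-12)
  expect_equal(exg$dxx_assoc[2], ctr_val("association", "right"), tolerance = 1e-12)
  # fully masked-out ROI is an error
  m2 <- const_maps
  m2$mask <- array(FALSE, dm)
  expect_error(extract_roi_diffusivities(m2, default_roi_set(geom)),
               "excluded")
})

test_that("the ALPS index is the printed mean ratio", {
  expect_equal(alps_index(1e-3, 1e-3, 1e-3, 1e-3), 1.0)
  expect_equal(alps_index(1.5e-3, 1.5e-3, 1.0e-3, 1.0e-3), 1.5)
  expect_equal(alps_index(1.6e-3, 1.4e-3, 1.1e-3, 0.9e-3), 1.5)
  expect_error(alps_index(1e-3, -1e-3, 1e-3, 1e-3), "positive")
  expect_error(alps_index(0, 1e-3, 1e-3, 1e-3), "positive")
})

test_that("the ALPS index is scale-invariant and strictly monotone", {
  set.seed(12)
  for (i in 1:50) {
    v <- runif(4, 0.5e-3, 2e-3)
    base <- alps_index(v[1], v[2], v[3], v[4])
    expect_equal(alps_index(v[1] * 3, v[2] * 3, v[3] * 3, v[4] * 3), base,
                 tolerance = 1e-12)
    eps <- 1e-5
    expect_gt(alps_index(v[1] + eps, v[2], v[3], v[4]), base)
    expect_gt(alps_index(v[1], v[2] + eps, v[3], v[4]), base)
    expect_lt(alps_index(v[1], v[2], v[3] + eps, v[4]), base)
    expect_lt(alps_index(v[1], v[2], v[3], v[4] + eps), base)
  }
})

test_that("bilateral index averages hemisphere indices, not diffusivities", {
  expect_equal(bilateral_alps(1.58, 1.58), 1.58)
  expect_equal(bilateral_alps(1.4, 1.6), 1.5)
  expect_error(bilateral_alps(1.4, NA), "hemisphere")

  geom <- test_geometry()
  truth <- list(
    left = c(dxx_proj = 1.2e-3, dxx_assoc = 1.2e-3,
             dyy_proj = 1.0e-3, dzz_assoc = 1.0e-3),
    right = c(dxx_proj = 1.8e-3, dxx_assoc = 1.8e-3,
              dyy_proj = 1.0e-3, dzz_assoc = 1.0e-3)
  )
  tf <- build_tensor_field(geom, truth)
  m <- measure_alps(compute_scalar_maps(tf), default_roi_set(geom),
                    voxel_size = geom$voxel_size)
  expect_equal(m$alps_left, 1.2, tolerance = 1e-12)
  expect_equal(m$alps_right, 1.8, tolerance = 1e-12)
  expect_equal(m$alps_bilateral, 1.5, tolerance = 1e-12)
  # oracle for the rejected convention: ratio of pooled diffusivities
  pooled <- alps_index(
    mean(c(truth$left["dxx_proj"], truth$right["dxx_proj"])),
    mean(c(truth$left["dxx_assoc"], truth$right["dxx_assoc"])),
    mean(c(truth$left["dyy_proj"], truth$right["dyy_proj"])),
    mean(c(truth$left["dzz_assoc"], truth$right["dzz_assoc"]))
  )
  expect_equal(pooled, 1.5) # coincides only because denominators match
  truth$right["dyy_proj"] <- 1.4e-3
  truth$right["dzz_assoc"] <- 1.4e-3
  tf2 <- build_tensor_field(geom, truth)
  m2 <- measure_alps(compute_scalar_maps(tf2), default_roi_set(geom),
                     voxel_size = geom$voxel_size)
  pooled2 <- alps_index(
    mean(c(truth$left["dxx_proj"], truth$right["dxx_proj"])),
    mean(c(truth$left["dxx_assoc"], truth$right["dxx_assoc"])),
    mean(c(truth$left["dyy_proj"], truth$right["dyy_proj"])),
    mean(c(truth$left["dzz_assoc"], truth$right["dzz_assoc"]))
  )
  expect_equal(m2$alps_bilateral, (1.2 + 1.8 / 1.4) / 2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m2$alps_bilateral, pooled2)))
})
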