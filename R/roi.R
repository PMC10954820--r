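#' The four spherical ALPS ROIs
#'
#' The ALPS method reads diffusivities from four small spherical ROIs
#' next to the lateral ventricle bodies: projection and association
#' region, in each hemisphere.  `default_roi_set()` returns the ROI
#' table at the phantom's template coordinates; centers can be shifted
#' per subject via `shift` to mirror manual placement adjustments.
#'
#' @param geometry a [phantom_geometry()].
#' @param diameter ROI diameter, mm (5.4 by default).
#' @param shift optional numeric length-3 (mm) added to every center, or
#'   a 4 x 3 matrix of per-ROI shifts (rows in the ROI-table order).
#' @return A tibble with columns region, hemisphere, x, y, z (mm),
#'   diameter.
#' @export
default_roi_set <- function(geometry, diameter = 5.4, shift = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"), diameter > 0)
  rois <- geometry$roi_centers
  if (!is.null(shift)) {
    sh <- if (is.matrix(shift)) shift else matrix(shift, 4, 3, byrow = TRUE)
    rois$x <- rois$x + sh[, 1]
    rois$y <- rois$y + sh[, 2]
    rois$z <- rois$z + sh[, 3]
  }
  rois$diameter <- diameter
  rois
}

#' Voxelize a spherical ROI
#'
#' Returns the logical mask of voxels whose centers lie within
#' `diameter / 2` (Euclidean distance in mm) of the ROI center.  No
#' partial-volume weighting: a voxel is in or out by its center.
#'
#' @param center numeric length-3, mm.
#' @param diameter sphere diameter, mm.
#' @param dim grid size (length 3) in voxels.
#' @param voxel_size voxel edge, mm.
#' @param label ROI name used in error messages.
#' @return Logical 3-D array.
#' @export
voxelize_roi <- function(center, diameter, dim, voxel_size, label = "ROI") {
  stopifnot(length(center) == 3, diameter > 0)
  co <- voxel_grid_mm(dim, voxel_size)
  if (any(center < c(0, 0, 0) - voxel_size / 2) ||
      any(center > c(max(co$x), max(co$y), max(co$z)) + voxel_size / 2)) {
    abort(sprintf("%s center (%.1f, %.1f, %.1f) mm lies outside the grid.",
                  label, center[1], center[2], center[3]))
  }
  r2 <- (diameter / 2)^2
  dx2 <- (co$x - center[1])^2
  dy2 <- (co$y - center[2])^2
  dz2 <- (co$z - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  m <- d2 <= r2
  if (!any(m)) abort(sprintf("%s mask is empty at diameter %.2f mm.", label, diameter))
  m
}

#' Extract ROI mean diffusivities for the ALPS index
#'
#' Computes, per hemisphere, the unweighted voxel means of Dxx over the
#' projection and association ROIs, Dyy over the projection ROI, and
#' Dzz over the association ROI.  Voxels outside the fit mask are
#' excluded; an ROI whose voxels are all excluded is an error.
#'
#' @param maps a `scalar_maps` object.
#' @param rois ROI tibble as from [default_roi_set()].
#' @param voxel_size voxel edge, mm (taken from `maps` if recorded).
#' @return A tibble with one row per hemisphere: columns hemisphere,
#'   dxx_proj, dxx_assoc, dyy_proj, dzz_assoc, n_proj, n_assoc.
#' @export
extract_roi_diffusivities <- function(maps, rois, voxel_size = NULL) {
  stopifnot(inherits(maps, "scalar_maps"))
  voxel_size <- voxel_size %||% maps$voxel_size
  if (is.null(voxel_size) || is.na(voxel_size)) {
    abort("`voxel_size` must be given when the maps do not record one.")
  }
  dm <- dim(maps$fa)
  roi_mean <- function(map, row) {
    lab <- paste(row$region, row$hemisphere)
    m <- voxelize_roi(c(row$x, row$y, row$z), row$diameter, dm, voxel_size,
                      label = lab)
    m <- m & maps$mask
    if (!any(m)) {
      abort(sprintf("all voxels of %s ROI are excluded by the mask.", lab))
    }
    c(mean = mean(map[m]), n = sum(m))
  }
  purrr::map_dfr(c("left", "right"), function(h) {
    proj <- rois[rois$region == "projection" & rois$hemisphere == h, ]
    asso <- rois[rois$region == "association" & rois$hemisphere == h, ]
    stopifnot(nrow(proj) == 1, nrow(asso) == 1)
    xp <- roi_mean(maps$dxx, proj)
    xa <- roi_mean(maps$dxx, asso)
    yp <- roi_mean(maps$dyy, proj)
    za <- roi_mean(maps$dzz, asso)
    tibble(hemisphere = h,
           dxx_proj = unname(xp["mean"]), dxx_assoc = unname(xa["mean"]),
           dyy_proj = unname(yp["mean"]), dzz_assoc = unname(za["mean"]),
           n_proj = as.integer(xp["n"]), n_assoc = as.integer(xa["n"]))
  })
}

#' ALPS index from the four ROI diffusivities
#'
#' The index is the ratio of the mean x-axis diffusivity in the
#' projection and association ROIs (the direction along the deep
#' medullary perivascular spaces, orthogonal to the fibers of both
#' regions) to the mean of the fiber-perpendicular diffusivities Dyy
#' (projection) and Dzz (association):
#' `mean(dxx_proj, dxx_assoc) / mean(dyy_proj, dzz_assoc)`.
#' A value near 1 indicates no preferential diffusion along the
#' perivascular axis.
#'
#' @param dxx_proj,dxx_assoc,dyy_proj,dzz_assoc positive diffusivities
#'   (mm^2/s); vectorised.
#' @return Numeric ALPS index.
#' @export
alps_index <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  vals <- cbind(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all four ROI diffusivities must be positive and finite (non-positive values signal an upstream fit failure).")
  }
  (dxx_proj + dxx_assoc) / (dyy_proj + dzz_assoc)
}

#' Bilateral ALPS index
#'
#' The arithmetic mean of the two hemisphere indices (not a ratio of
#' diffusivities pooled across hemispheres).
#'
#' @param left,right hemisphere ALPS indices.
#' @return Numeric.
#' @export
bilateral_alps <- function(left, right) {
  if (length(left) != length(right) || any(!is.finite(c(left, right)))) {
    abort("both hemisphere indices are required; no single-hemisphere fallback.")
  }
  (left + right) / 2
}

#' Per-subject ALPS measurement from scalar maps
#'
#' Convenience wrapper: extracts the four ROI diffusivities per
#' hemisphere, computes the hemisphere indices and the bilateral mean.
#'
#' @inheritParams extract_roi_diffusivities
#' @return One-row tibble: per-hemisphere diffusivities and indices
#'   (wide, `_left`/`_right` suffixes), plus `alps_left`, `alps_right`,
#'   `alps_bilateral` and ROI voxel counts.
#' @export
measure_alps <- function(maps, rois, voxel_size = NULL) {
  ex <- extract_roi_diffusivities(maps, rois, voxel_size)
  idx <- alps_index(ex$dxx_proj, ex$dxx_assoc, ex$dyy_proj, ex$dzz_assoc)
  wide <- tidyr::pivot_wider(
    cbind(ex, alps = idx),
    names_from = "hemisphere",
    values_from = c("dxx_proj", "dxx_assoc", "dyy_proj", "dzz_assoc",
                    "n_proj", "n_assoc", "alps")
  )
  wide$alps_bilateral <- bilateral_alps(wide$alps_left, wide$alps_right)
  as_tibble(wide)
}
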