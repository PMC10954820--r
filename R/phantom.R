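#' Phantom geometry for the ALPS ROI layout
#'
#' Builds a digital phantom in RAS orientation that reproduces, in
#' idealised form, the periventricular geometry the ALPS method relies
#' on: a CSF-filled ventricle slab on the midline, flanked in each
#' hemisphere by a projection-fiber band (principal fibers along z, as in
#' the corona radiata) and, further laterally, an association-fiber band
#' (principal fibers along y, as in the superior longitudinal
#' fasciculus).  The x axis (right-left) is orthogonal to the fibers in
#' both bands, which is what lets x-axis diffusivity act as a
#' perivascular-flow readout.
#'
#' Voxel (i, j, k) (1-based) has its center at ((i-1), (j-1), (k-1)) *
#' `voxel_size` mm; the affine is a pure scaling.  Region bands are
#' symmetric slabs around the grid center: ventricle |dx| <= 7.2 mm,
#' projection 7.2 < |dx| <= 21.6 mm, association 21.6 < |dx| <= 36 mm,
#' each restricted to |dy|, |dz| <= 18 mm.  Default ROI centers sit on
#' voxel centers at dx = +/-14.4 mm (projection) and +/-28.8 mm
#' (association), so a 5.4 mm sphere lies strictly inside its band.
#'
#' @param dim grid size in voxels (scalar or length 3); >= 44 so the
#'   association band fits inside the grid.
#' @param voxel_size isotropic voxel edge, mm.
#' @return An object of class `phantom_geometry`: list with `dim`,
#'   `voxel_size`, integer `labels` array (codes in `alps_region_codes`),
#'   and `roi_centers`, a tibble of the four default ROI centers (mm).
#' @examples
#' geom <- phantom_geometry(dim = 44)
#' table(geom$labels)
#' @export
phantom_geometry <- function(dim = 64, voxel_size = 1.8) {
  if (length(dim) == 1) dim <- rep(dim, 3)
  stopifnot(length(dim) == 3, voxel_size > 0)
  extent_needed <- 36 + voxel_size # association band + one voxel margin
  if (any((dim / 2) * voxel_size < extent_needed)) {
    abort(sprintf(
      "grid too small: half-extent must cover %.1f mm (need >= %d voxels at %.1f mm).",
      extent_needed, ceiling(2 * extent_needed / voxel_size), voxel_size
    ))
  }
  ctr <- (dim / 2) * voxel_size # a voxel center when dim is even
  co <- voxel_grid_mm(dim, voxel_size)
  dx <- co$x - ctr[1]
  dy <- co$y - ctr[2]
  dz <- co$z - ctr[3]

  labels <- array(alps_region_codes["background"], dim = dim)
  in_slab <- outer(abs(dy) <= 18, abs(dz) <= 18, "&") # ny x nz
  slab <- aperm(array(in_slab, dim = c(dim[2], dim[3], dim[1])), c(3, 1, 2))
  axd <- array(abs(dx), dim = dim)
  sgn <- array(sign(dx), dim = dim) # -1 = left (lower x in RAS)
  labels[slab & axd <= 7.2] <- alps_region_codes["ventricle"]
  proj <- slab & axd > 7.2 & axd <= 21.6
  asso <- slab & axd > 21.6 & axd <= 36
  labels[proj & sgn < 0] <- alps_region_codes["projection_left"]
  labels[proj & sgn > 0] <- alps_region_codes["projection_right"]
  labels[asso & sgn < 0] <- alps_region_codes["association_left"]
  labels[asso & sgn > 0] <- alps_region_codes["association_right"]

  roi_centers <- tibble(
    region = rep(c("projection", "association"), each = 2),
    hemisphere = rep(c("left", "right"), 2),
    x = ctr[1] + c(-14.4, 14.4, -28.8, 28.8),
    y = ctr[2], z = ctr[3]
  )
  structure(
    list(dim = dim, voxel_size = voxel_size, labels = labels,
         roi_centers = roi_centers),
    class = "phantom_geometry"
  )
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("<phantom_geometry> %s voxels at %.1f mm\n",
              paste(x$dim, collapse = "x"), x$voxel_size))
  invisible(x)
}

#' @rdname phantom_geometry
#' @format `alps_region_codes` is a named integer vector of label codes
#'   used in the geometry's `labels` array.
#' @export
alps_region_codes <- c(
  background = 0L, ventricle = 1L,
  projection_left = 2L, projection_right = 3L,
  association_left = 4L, association_right = 5L
)

# voxel-center world coordinates (mm) along each axis
voxel_grid_mm <- function(dim, voxel_size) {
  list(x = (seq_len(dim[1]) - 1) * voxel_size,
       y = (seq_len(dim[2]) - 1) * voxel_size,
       z = (seq_len(dim[3]) - 1) * voxel_size)
}

#' Build a ground-truth diffusion tensor field on a phantom
#'
#' Fills each labeled region with a diagonal tensor carrying the
#' subject's ground-truth diffusivities.  Projection voxels get
#' diag(dxx_proj, dyy_proj, axial): the principal (axial) eigenvalue on
#' z.  Association voxels get diag(dxx_assoc, axial, dzz_assoc):
#' principal eigenvalue on y.  The ventricle is isotropic CSF-like and
#' the background isotropic parenchyma.  Supplying different `left` and
#' `right` diffusivities produces a hemispherically asymmetric subject.
#'
#' @param geometry a [phantom_geometry()].
#' @param diffusivities named numeric vector with elements `dxx_proj`,
#'   `dxx_assoc`, `dyy_proj`, `dzz_assoc` (mm^2/s), applied to both
#'   hemispheres, or a list with elements `left` and `right` each such a
#'   vector.
#' @param axial axial (principal-fiber) diffusivity of the fiber bands,
#'   mm^2/s.  Set equal to the perpendicular diffusivities to make ROI
#'   voxels fully isotropic.
#' @param background,ventricle isotropic diffusivities of parenchyma and
#'   CSF, mm^2/s.
#' @return A `tensor_field`: list with `d`, an nx x ny x nz x 6 array of
#'   tensor elements in the order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz); `s0`,
#'   the unweighted signal (1 everywhere); `mask` (all TRUE); `voxel_size`.
#' @export
build_tensor_field <- function(geometry, diffusivities,
                               axial = 1.7e-3,
                               background = 0.8e-3,
                               ventricle = 3.0e-3) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  hemi <- normalize_truth(diffusivities)
  for (h in c("left", "right")) {
    dv <- hemi[[h]]
    if (any(!is.finite(dv)) || any(dv <= 0) || axial <= 0 ||
        background <= 0 || ventricle <= 0) {
      abort("all diffusivities must be positive and finite (tensor must be positive-definite).")
    }
  }
  dm <- geometry$dim
  d <- array(0, dim = c(dm, 6))
  lab <- geometry$labels
  # start from isotropic background, then paint regions
  for (el in c(1L, 4L, 6L)) d[, , , el] <- background
  set_region <- function(code, dxx, dyy, dzz) {
    idx <- lab == code
    dxx_a <- d[, , , 1]; dxx_a[idx] <- dxx; d[, , , 1] <<- dxx_a
    dyy_a <- d[, , , 4]; dyy_a[idx] <- dyy; d[, , , 4] <<- dyy_a
    dzz_a <- d[, , , 6]; dzz_a[idx] <- dzz; d[, , , 6] <<- dzz_a
  }
  set_region(alps_region_codes["ventricle"], ventricle, ventricle, ventricle)
  set_region(alps_region_codes["projection_left"],
             hemi$left["dxx_proj"], hemi$left["dyy_proj"], axial)
  set_region(alps_region_codes["projection_right"],
             hemi$right["dxx_proj"], hemi$right["dyy_proj"], axial)
  set_region(alps_region_codes["association_left"],
             hemi$left["dxx_assoc"], axial, hemi$left["dzz_assoc"])
  set_region(alps_region_codes["association_right"],
             hemi$right["dxx_assoc"], axial, hemi$right["dzz_assoc"])
  new_tensor_field(d, s0 = array(1, dim = dm),
                   mask = array(TRUE, dim = dm),
                   voxel_size = geometry$voxel_size)
}

truth_elements <- c("dxx_proj", "dxx_assoc", "dyy_proj", "dzz_assoc")

normalize_truth <- function(diffusivities) {
  as_vec <- function(v) {
    if (!all(truth_elements %in% names(v))) {
      abort(paste0("diffusivities must name ",
                   paste(truth_elements, collapse = ", "), "."))
    }
    unlist(v)[truth_elements]
  }
  if (is.list(diffusivities) && !is.null(diffusivities$left)) {
    list(left = as_vec(diffusivities$left), right = as_vec(diffusivities$right))
  } else {
    v <- as_vec(diffusivities)
    list(left = v, right = v)
  }
}

new_tensor_field <- function(d, s0, mask, voxel_size, n_clamped = 0L) {
  structure(list(d = d, s0 = s0, mask = mask, voxel_size = voxel_size,
                 n_clamped = n_clamped),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  dm <- dim(x$d)
  cat(sprintf("<tensor_field> %s voxels (%d in mask) at %.1f mm\n",
              paste(dm[1:3], collapse = "x"), sum(x$mask), x$voxel_size))
  invisible(x)
}

#' Simulate a diffusion-weighted volume from a tensor field
#'
#' Applies the monoexponential Stejskal-Tanner forward model per voxel
#' and volume, S = S0 * exp(-b g' D g), then magnitude (Rician) noise:
#' sqrt((S + e1)^2 + e2^2) with e1, e2 ~ Normal(0, noise_sigma * S0).
#' The noise level is expressed relative to the unweighted signal, so
#' `noise_sigma = 0.01` is an SNR-100 acquisition at b = 0.
#'
#' @param tensor_field a `tensor_field` (see [build_tensor_field()]).
#' @param scheme an `alps_scheme`.
#' @param noise_sigma Rician noise SD as a fraction of the b = 0 signal.
#' @param seed integer seed; the volume is a pure function of
#'   (tensor_field, scheme, noise_sigma, seed).
#' @return A numeric 4-D array (nx, ny, nz, n_volumes).
#' @export
simulate_dwi <- function(tensor_field, scheme, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(tensor_field, "tensor_field"))
  validate_scheme(scheme)
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  dm <- dim(tensor_field$d)[1:3]
  nvox <- prod(dm)
  nvol <- length(scheme$bvals)
  dmat <- matrix(tensor_field$d, nrow = nvox, ncol = 6)
  g <- scheme$bvecs
  # quadratic-form coefficients matching element order (xx,xy,xz,yy,yz,zz)
  gq <- cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
              g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2)
  expo <- dmat %*% t(gq * scheme$bvals) # nvox x nvol
  s0 <- as.vector(tensor_field$s0)
  sig <- s0 * exp(-expo)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    sd_n <- noise_sigma * s0
    e1 <- matrix(rnorm(nvox * nvol, sd = sd_n), nvox, nvol)
    e2 <- matrix(rnorm(nvox * nvol, sd = sd_n), nvox, nvol)
    sig <- sqrt((sig + e1)^2 + e2^2)
  }
  array(sig, dim = c(dm, nvol))
}
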