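#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti keeping the phantom's isotropic voxel
#' size in the header.  Volumes are stored as 32-bit float.
#'
#' @param x 3-D or 4-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size isotropic voxel edge, mm.
#' @return `read_volume()` returns a plain array with attribute
#'   `voxel_size`.
#' @export
write_volume <- function(x, path, voxel_size) {
  im <- RNifti::asNifti(x)
  nd <- length(dim(x))
  RNifti::pixdim(im) <- c(rep(voxel_size, 3), rep(1, nd - 3))
  RNifti::writeNifti(im, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  out <- array(as.numeric(im), dim = dim(im))
  attr(out, "voxel_size") <- RNifti::pixdim(im)[1]
  out
}

write_roi_json <- function(rois, path) {
  jsonlite::write_json(rois, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

read_roi_json <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

# manifest: md5 per written file, plus seed and config echo
write_manifest <- function(dir, files, config) {
  hashes <- tools::md5sum(files)
  manifest <- list(
    seed = config$cohort$master_seed,
    config = unclass_deep(config),
    files = as.list(setNames(unname(hashes), basename(names(hashes))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
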