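#' Diffusion acquisition schemes
#'
#' An acquisition scheme pairs one b-value with one (unit) gradient
#' direction per volume.  b = 0 volumes carry a zero direction vector.
#' The default scheme mirrors a single-shell clinical protocol:
#' one b = 0 volume followed by 64 directions at b = 1000 s/mm^2.
#'
#' Directions are spread quasi-uniformly over the sphere with a Fibonacci
#' (golden-angle) spiral, which is deterministic and leaves the tensor
#' design matrix full rank for any n >= 6.
#'
#' @param n_directions number of diffusion-weighted directions.
#' @param bvalue diffusion weighting in s/mm^2 for the weighted volumes.
#' @param n_b0 number of unweighted (b = 0) volumes, prepended.
#' @return An object of class `alps_scheme`: a list with numeric vector
#'   `bvals` (length n volumes) and an n x 3 matrix `bvecs` of unit
#'   directions (zero rows for b = 0 volumes).
#' @examples
#' sch <- make_scheme()
#' length(sch$bvals)
#' @export
make_scheme <- function(n_directions = 64, bvalue = 1000, n_b0 = 1) {
  stopifnot(n_directions >= 6, n_b0 >= 1, bvalue > 0)
  dirs <- fibonacci_sphere(n_directions)
  bvals <- c(rep(0, n_b0), rep(bvalue, n_directions))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  structure(list(bvals = bvals, bvecs = bvecs), class = "alps_scheme")
}

# Quasi-uniform points on S^2 by the golden-angle spiral.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @export
print.alps_scheme <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat(sprintf(
    "<alps_scheme> %d volumes: %d b=0, %d directions at b=%g s/mm^2\n",
    length(x$bvals), nb0, length(x$bvals) - nb0, max(x$bvals)
  ))
  invisible(x)
}

validate_scheme <- function(scheme) {
  if (!inherits(scheme, "alps_scheme")) {
    abort("`scheme` must be an `alps_scheme` (see make_scheme()).")
  }
  n <- length(scheme$bvals)
  if (n < 7 || sum(scheme$bvals == 0) < 1) {
    abort("scheme needs >= 7 volumes including >= 1 with b = 0 (7 unknowns).")
  }
  if (!is.matrix(scheme$bvecs) || nrow(scheme$bvecs) != n ||
      ncol(scheme$bvecs) != 3) {
    abort("scheme `bvecs` must be an n x 3 matrix matching `bvals`.")
  }
  dw <- scheme$bvals > 0
  norms <- sqrt(rowSums(scheme$bvecs[dw, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort("non-b0 gradient directions must be unit vectors (|norm - 1| <= 1e-6).")
  }
  invisible(scheme)
}

#' Read and write FSL-style bval/bvec files
#'
#' `write_bval_bvec()` writes the scheme as a single-line whitespace
#' separated bval file and a three-row bvec file (x, y, z rows), the
#' dialect used by FSL's `dtifit`.  `read_bval_bvec()` reads it back.
#'
#' @param scheme an `alps_scheme`.
#' @param bval_path,bvec_path file paths.
#' @return `read_bval_bvec()` returns an `alps_scheme`.
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  validate_scheme(scheme)
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  rows <- apply(t(scheme$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(c(bval = bval_path, bvec = bvec_path))
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- t(as.matrix(utils::read.table(bvec_path)))
  dimnames(bvecs) <- NULL
  structure(list(bvals = bvals, bvecs = bvecs), class = "alps_scheme")
}
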