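#' Scalar, spherical-harmonic and peak volumes
#'
#' Three thin S3 containers around dense arrays plus a voxel-to-world
#' [affine()]:
#'
#' * `scalar_volume`: a 3D grid of reals (FA, GFA, T1, masks). Supplies the
#'   tracking weight `f` and the stopping mask.
#' * `sh_volume`: a 4D grid whose last axis holds the
#'   `(lmax+1)(lmax+2)/2` coefficients of a real, symmetric (even-degree)
#'   spherical-harmonic basis (45 for `lmax = 8`).
#' * `peak_field`: a 4D grid whose last axis is 15 (five direction triplets)
#'   or 20 (five direction triplets each followed by an uncertainty
#'   half-angle alpha, radians). Unused peak slots are all-zero; stored
#'   directions are unit vectors in world (RAS) axes.
#'
#' @param data the array (3D or 4D as appropriate).
#' @param affine an [affine()].
#' @param lmax even, non-negative SH order.
#' @param has_alpha whether the last axis carries alpha values (inferred
#'   from the last-axis length when `NULL`).
#' @return an object of class `scalar_volume`, `sh_volume` or `peak_field`.
#' @name volumes
NULL

#' @rdname volumes
#' @export
scalar_volume <- function(data, affine) {
  stopifnot(length(dim(data)) == 3L, all(dim(data) > 0L), all(is.finite(data)))
  structure(list(data = data, affine = affine), class = "scalar_volume")
}

#' @rdname volumes
#' @export
sh_volume <- function(data, affine, lmax) {
  stopifnot(length(dim(data)) == 4L, lmax >= 0L, lmax %% 2L == 0L)
  if (dim(data)[4L] != n_sh_coeffs(lmax))
    stop(sprintf("last axis is %d but lmax = %d needs %d coefficients",
                 dim(data)[4L], lmax, n_sh_coeffs(lmax)))
  structure(list(data = data, affine = affine, lmax = as.integer(lmax)),
            class = "sh_volume")
}

n_sh_coeffs <- function(lmax) as.integer((lmax + 1L) * (lmax + 2L) / 2L)

#' @rdname volumes
#' @export
peak_field <- function(data, affine, has_alpha = NULL) {
  stopifnot(length(dim(data)) == 4L)
  nlast <- dim(data)[4L]
  if (!nlast %in% c(15L, 20L))
    stop(sprintf("peak volume last axis must be 15 or 20, got %d", nlast))
  if (is.null(has_alpha)) has_alpha <- nlast == 20L
  stopifnot(identical(has_alpha, nlast == 20L))
  structure(list(data = data, affine = affine, has_alpha = has_alpha),
            class = "peak_field")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %s, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.sh_volume <- function(x, ...) {
  cat(sprintf("<sh_volume %s, lmax = %d>\n",
              paste(dim(x$data), collapse = " x "), x$lmax))
  invisible(x)
}

#' @export
print.peak_field <- function(x, ...) {
  cat(sprintf("<peak_field %s, up to 5 peaks/voxel, alpha: %s>\n",
              paste(dim(x$data)[1:3], collapse = " x "),
              if (x$has_alpha) "yes" else "no"))
  invisible(x)
}

#' Peaks of one voxel as a matrix
#'
#' @param field a [peak_field()].
#' @param voxel integer voxel index, 0-based, length 3.
#' @return a list with `directions` (m x 3 matrix of unit vectors, m <= 5)
#'   and `alpha` (length-m vector, radians; zeros when the field has no
#'   alpha axis).
#' @export
peaks_at_voxel <- function(field, voxel) {
  d <- dim(field$data)[1:3]
  stopifnot(all(voxel >= 0L), all(voxel <= d - 1L))
  v <- field$data[voxel[1L] + 1L, voxel[2L] + 1L, voxel[3L] + 1L, ]
  stride <- if (field$has_alpha) 4L else 3L
  m <- matrix(v, ncol = stride, byrow = TRUE)
  keep <- rowSums(abs(m[, 1:3, drop = FALSE])) > 0
  list(directions = m[keep, 1:3, drop = FALSE],
       alpha = if (field$has_alpha) m[keep, 4L] else rep(0, sum(keep)))
}

# ---- NIfTI I/O -------------------------------------------------------------

nifti_affine <- function(img) {
  x <- RNifti::xform(img, useQuaternionFirst = FALSE)  # sform is authoritative
  affine(matrix(as.numeric(x), 4L, 4L))
}

write_nifti_with_affine <- function(data, aff, path) {
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(affine_voxel_size(aff), rep(1, nd - 3L))
  m <- unclass(aff)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write volumes as NIfTI-1
#'
#' `read_scalar_volume` expects a 3D image; `read_sh_volume` a 4D image whose
#' last axis matches an even SH order; `read_peaks` a 4D image whose last
#' axis is 15 (directions only) or 20 (directions + alpha). Directions whose
#' norm deviates from 1 by more than 1e-3 are renormalised on read (all-zero
#' slots are preserved as absent peaks). Alphas are radians on disk.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol,field the object to write.
#' @param lmax SH order of the file; inferred from the last-axis length when
#'   `NULL`.
#' @return the volume object, or (for writers) the path, invisibly.
#' @export
read_scalar_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3D volume, got %dD (use read_sh_volume/read_peaks for 4D)",
                 length(dim(img))))
  scalar_volume(array(as.numeric(img), dim(img)), nifti_affine(img))
}

#' @rdname read_scalar_volume
#' @export
write_scalar_volume <- function(vol, path) {
  write_nifti_with_affine(vol$data, vol$affine, path)
}

#' @rdname read_scalar_volume
#' @export
read_sh_volume <- function(path, lmax = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4D SH-coefficient volume")
  nc <- dim(img)[4L]
  if (is.null(lmax)) {
    # invert nc = (lmax+1)(lmax+2)/2 for even lmax
    lmax <- (sqrt(8 * nc + 1) - 3) / 2
    if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
      stop(sprintf("last-axis length %d does not match any even SH order", nc))
    lmax <- as.integer(round(lmax))
  }
  sh_volume(array(as.numeric(img), dim(img)), nifti_affine(img), lmax)
}

#' @rdname read_scalar_volume
#' @export
write_sh_volume <- function(vol, path) {
  write_nifti_with_affine(vol$data, vol$affine, path)
}

#' @rdname read_scalar_volume
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4D peaks volume")
  nlast <- dim(img)[4L]
  if (!nlast %in% c(15L, 20L))
    stop(sprintf("peaks volume last axis must be 15 or 20, got %d", nlast))
  data <- array(as.numeric(img), dim(img))
  has_alpha <- nlast == 20L
  stride <- if (has_alpha) 4L else 3L
  nvox <- prod(dim(data)[1:3])
  m <- matrix(data, nrow = nvox)
  for (s in 0:4) {
    cols <- s * stride + 1:3
    nrm <- sqrt(rowSums(m[, cols, drop = FALSE]^2))
    fix <- nrm > 0 & abs(nrm - 1) > 1e-3
    if (any(fix)) m[fix, cols] <- m[fix, cols, drop = FALSE] / nrm[fix]
  }
  peak_field(array(m, dim(data)), nifti_affine(img), has_alpha)
}

#' @rdname read_scalar_volume
#' @export
write_peaks <- function(field, path) {
  write_nifti_with_affine(field$data, field$affine, path)
}
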