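#' Voxel-to-world affine transforms
#'
#' A 4x4 matrix mapping 0-based voxel indices to world coordinates in mm
#' (RAS orientation). The package-wide convention is: voxel indices are
#' 0-based, a voxel's centre sits at integer voxel coordinates, and "the
#' voxel at position p" means element-wise rounding of [world_to_voxel()].
#' (R arrays are 1-based, so voxel (i, j, k) lives at `data[i+1, j+1, k+1]`.)
#'
#' @param matrix a 4x4 numeric matrix; last row must be (0, 0, 0, 1).
#' @return an object of class `ct_affine` (a plain 4x4 matrix).
#' @examples
#' a <- affine(diag(c(1.72, 1.72, 1.72, 1)))
#' world_to_voxel(c(1.72, 0, 0), a) # voxel (1, 0, 0)
#' @export
affine <- function(matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(is.numeric(matrix), all(dim(matrix) == c(4L, 4L)))
  if (max(abs(matrix[4L, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("affine last row must be (0, 0, 0, 1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine is singular")
  structure(matrix, class = "ct_affine")
}

#' @export
print.ct_affine <- function(x, ...) {
  cat("<voxel-to-world affine (mm, RAS)>\n")
  print(unclass(x))
  invisible(x)
}

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Points are given as a length-3 vector or an n x 3 matrix; the result has
#' the same shape. `world_to_voxel` applies the inverse affine,
#' `voxel_to_world` the forward affine. The round trip is the identity to
#' well below 1e-6 voxel.
#'
#' @param p points, length-3 vector or n x 3 matrix.
#' @param a an [affine()].
#' @return coordinates with the same shape as `p`.
#' @export
world_to_voxel <- function(p, a) {
  apply_affine(p, solve(unclass(a)))
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(p, a) {
  apply_affine(p, unclass(a))
}

apply_affine <- function(p, m) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    drop(m[1:3, 1:3] %*% p + m[1:3, 4L])
  } else {
    stopifnot(ncol(p) == 3L)
    sweep(p %*% t(m[1:3, 1:3]), 2L, m[1:3, 4L], `+`)
  }
}

#' @description `voxel_at` rounds continuous voxel coordinates to the integer
#'   voxel owning a world point (voxel centres at integer coordinates).
#' @rdname world_to_voxel
#' @export
voxel_at <- function(p, a) {
  v <- world_to_voxel(p, a)
  if (is.null(dim(v))) round(v) else round(v)
}

# voxel sizes = column norms of the linear part
affine_voxel_size <- function(a) {
  sqrt(colSums(unclass(a)[1:3, 1:3]^2))
}
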