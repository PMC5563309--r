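#' Peak extraction parameters
#'
#' @param relative_threshold fraction of the global maximum below which local
#'   maxima are discarded (default 0.5).
#' @param min_separation_angle minimum pairwise angular separation between
#'   returned peaks, degrees (default 25).
#' @param max_peaks at most this many peaks per fODF, <= 5 (default 5).
#' @param fwhm_fraction fraction k of a peak's value at which its angular
#'   width — the uncertainty half-angle alpha — is measured (default 0.35;
#'   1 gives alpha = 0 up to mesh resolution, smaller k gives wider cones).
#' @return a list of class `peak_extraction_params`.
#' @export
peak_extraction_params <- function(relative_threshold = 0.5,
                                   min_separation_angle = 25,
                                   max_peaks = 5L,
                                   fwhm_fraction = 0.35) {
  stopifnot(relative_threshold > 0, relative_threshold < 1,
            min_separation_angle >= 0,
            max_peaks >= 1L, max_peaks <= 5L,
            fwhm_fraction > 0, fwhm_fraction <= 1)
  structure(list(relative_threshold = relative_threshold,
                 min_separation_angle = min_separation_angle,
                 max_peaks = as.integer(max_peaks),
                 fwhm_fraction = fwhm_fraction),
            class = "peak_extraction_params")
}

#' Find the peaks of a spherical function
#'
#' A peak is a vertex no neighbour of which has a larger value and at least
#' one neighbour of which has a strictly smaller one. Exact ties — which
#' arise when a lobe's axis falls on a symmetry plane of the mesh — still
#' count as maxima (the tied pair collapses in the suppression step), while
#' constant plateaus such as an isotropic function yield no peaks. Maxima are
#' filtered to `relative_threshold` x the global maximum, sorted by
#' descending value, and greedily suppressed so that any two returned peaks
#' are at least `min_separation_angle` apart, with angles measured between
#' axes, i.e. min(theta, 180 - theta) — which also collapses each antipodal
#' pair to its stronger representative.
#'
#' @param f a [spherical_function()].
#' @param params a [peak_extraction_params()].
#' @return a data.frame with columns `vertex` (index), `value`, `x`, `y`,
#'   `z`; zero rows when nothing qualifies.
#' @export
find_peaks_on_sphere <- function(f, params = peak_extraction_params()) {
  mesh <- f$mesh
  vals <- f$values
  is_max <- vapply(seq_along(vals), function(i) {
    nb <- vals[mesh$adjacency[[i]]]
    all(vals[i] >= nb) && any(vals[i] > nb)
  }, logical(1))
  kept <- select_peak_vertices(f, which(is_max), params)
  data.frame(vertex = kept, value = vals[kept],
             x = mesh$vertices[kept, 1], y = mesh$vertices[kept, 2],
             z = mesh$vertices[kept, 3])
}

#' Uncertainty half-angle of a peak at a fractional threshold
#'
#' Starting from the peak vertex, vertices within 90 degrees are visited in
#' increasing angular distance (the breadth-first cap traversal); alpha is
#' the angular distance to the first vertex whose value falls strictly below
#' `k` times the peak value. If no vertex within 90 degrees falls below the
#' fraction (a plateau or near-isotropic lobe), alpha is capped at pi/2 so a
#' probabilistic cone degrades gracefully to a hemisphere.
#'
#' @param f a [spherical_function()].
#' @param peak_vertex vertex index of a local maximum of `f`.
#' @param k fraction in (0, 1].
#' @return alpha in radians, in `[0, pi/2]`.
#' @export
uncertainty_angle <- function(f, peak_vertex, k) {
  if (k <= 0 || k > 1) stop("k must be in (0, 1]")
  ord <- mesh_angle_order(f$mesh, peak_vertex)
  cutoff <- k * f$values[peak_vertex]
  within <- ord$angle <= pi / 2 + 1e-12
  idx <- ord$order[within]
  ang <- ord$angle[within]
  below <- f$values[idx] < cutoff
  below[1L] <- FALSE  # the peak itself
  hit <- which(below)[1L]
  if (is.na(hit)) pi / 2 else ang[hit]
}

#' Extract a peak field (with uncertainty angles) from an SH fODF volume
#'
#' Per voxel: evaluate the fODF on the mesh, find up to `max_peaks` peaks,
#' and measure each peak's uncertainty half-angle alpha at fraction
#' `fwhm_fraction`; the result is a [peak_field()] with alphas (last axis
#' 20). Voxels outside the mask (mask value below `mask_threshold`) are
#' all-zero.
#'
#' @param v an [sh_volume()].
#' @param mesh a [make_icosphere()] mesh.
#' @param params a [peak_extraction_params()].
#' @param mask optional [scalar_volume()] on the same grid.
#' @param mask_threshold minimum mask value for a voxel to be processed.
#' @return a [peak_field()] with `has_alpha = TRUE`.
#' @export
peaks_from_sh_volume <- function(v, mesh, params = peak_extraction_params(),
                                 mask = NULL, mask_threshold = 0.1) {
  dims <- dim(v$data)
  if (!is.null(mask) && !all(dim(mask$data) == dims[1:3]))
    stop("mask grid does not match the SH volume")
  nvox <- prod(dims[1:3])
  coeffs <- matrix(v$data, nrow = nvox)            # row = linear voxel index
  in_mask <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask$data) >= mask_threshold
  in_mask <- in_mask & rowSums(abs(coeffs)) > 0
  out <- matrix(0, nvox, 20L)
  B <- cached_basis(mesh, v$lmax)
  idx <- which(in_mask)
  if (length(idx)) {
    vals <- coeffs[idx, , drop = FALSE] %*% t(B)   # n_active x n_vertices
    # local maxima, vectorised over voxels: no neighbour larger, at least one
    # strictly smaller (see find_peaks_on_sphere)
    nmax <- matrix(-Inf, length(idx), nrow(mesh$vertices))
    nmin <- matrix(Inf, length(idx), nrow(mesh$vertices))
    for (j in seq_len(nrow(mesh$vertices))) {
      for (nb in mesh$adjacency[[j]]) {
        nmax[, j] <- pmax(nmax[, j], vals[, nb])
        nmin[, j] <- pmin(nmin[, j], vals[, nb])
      }
    }
    ismax <- vals >= nmax & vals > nmin
    for (r in seq_along(idx)) {
      f <- structure(list(values = vals[r, ], mesh = mesh),
                     class = "spherical_function")
      pk <- select_peak_vertices(f, which(ismax[r, ]), params)
      if (!length(pk)) next
      row <- numeric(20L)
      for (s in seq_along(pk)) {
        a <- uncertainty_angle(f, pk[s], params$fwhm_fraction)
        row[(s - 1L) * 4L + 1:4] <- c(mesh$vertices[pk[s], ], a)
      }
      out[idx[r], ] <- row
    }
  }
  peak_field(array(out, c(dims[1:3], 20L)), v$affine, has_alpha = TRUE)
}

# thresholding + antipode dedup + greedy angular suppression on a
# precomputed candidate set (shared by the vectorised volume path)
select_peak_vertices <- function(f, cand, params) {
  mesh <- f$mesh
  vals <- f$values
  cand <- cand[vals[cand] >= params$relative_threshold * max(vals)]
  cand <- cand[order(vals[cand], decreasing = TRUE)]
  # axial suppression: the angle between a vertex and its antipode is 0, so
  # this also collapses each +/- pair to its stronger representative
  min_sep <- max(params$min_separation_angle * pi / 180, 1e-6)
  kept <- integer()
  for (i in cand) {
    if (length(kept) >= params$max_peaks) break
    if (length(kept)) {
      dots <- abs(drop(mesh$vertices[kept, , drop = FALSE] %*% mesh$vertices[i, ]))
      if (any(acos(pmin(dots, 1)) < min_sep)) next
    }
    kept <- c(kept, i)
  }
  kept
}
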