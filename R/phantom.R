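#' Synthetic fiber phantom specification
#'
#' Phantoms emulate everything a real evaluation dataset supplies: an FA
#' map, a peak field with uncertainty angles, an SH fODF volume and
#' analytic ground-truth centreline bundles. The single-fiber profile is a
#' Gaussian in angle, `exp(-theta^2 / (2 sigma^2))` (symmetrised over
#' antipodes), chosen because the angle at which it crosses a fraction k of
#' its peak has the closed form `sigma * sqrt(2 ln(1/k))` — the analytic
#' oracle the uncertainty-angle extraction is tested against. The default
#' grid is 40^3 voxels at 1.72 mm, mirroring the spacing of the evaluation
#' data the method was demonstrated on, but small enough for seconds-scale
#' runs.
#'
#' @param shape integer voxel counts (length 3).
#' @param voxel_size isotropic voxel size, mm.
#' @param geometry `"straight"`, `"curved"` or `"crossing"`.
#' @param fa_inside,fa_outside scalar-map values inside/outside the bundle
#'   (inside must exceed outside).
#' @param kernel_sigma angular width sigma of the single-fiber profile,
#'   degrees.
#' @param crossing_angle angle between the two crossing bundles, degrees.
#' @param curve_radius radius of the curved bundle's arc, mm.
#' @param bundle_radius tube radius of each bundle, mm.
#' @param fwhm_fraction fraction k at which the stored uncertainty angles
#'   are computed (alpha = sigma * sqrt(2 ln(1/k))).
#' @param lmax SH order of the fODF volume.
#' @param rng_seed kept for interface symmetry; phantom generation is
#'   deterministic.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 40L, 40L), voxel_size = 1.72,
                         geometry = c("straight", "curved", "crossing"),
                         fa_inside = 0.8, fa_outside = 0.02,
                         kernel_sigma = 20, crossing_angle = 90,
                         curve_radius = 20, bundle_radius = 6,
                         fwhm_fraction = 0.35, lmax = 8L, rng_seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(length(shape) == 3L, all(shape > 0L), voxel_size > 0,
            fa_inside > fa_outside, kernel_sigma > 0,
            bundle_radius > 0, curve_radius > 0,
            fwhm_fraction > 0, fwhm_fraction <= 1)
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 geometry = geometry, fa_inside = fa_inside,
                 fa_outside = fa_outside, kernel_sigma = kernel_sigma,
                 crossing_angle = crossing_angle, curve_radius = curve_radius,
                 bundle_radius = bundle_radius,
                 fwhm_fraction = fwhm_fraction, lmax = as.integer(lmax),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Closed-form uncertainty angle of the Gaussian angular profile
#'
#' The angle at which `exp(-theta^2 / (2 sigma^2))` falls to fraction `k`
#' of its peak: `sigma * sqrt(2 ln(1/k))`. Returns 0 for `k = 1`.
#'
#' @param sigma profile width, degrees.
#' @param k fraction in (0, 1]; vectorised.
#' @return the angle in degrees.
#' @export
analytic_alpha <- function(sigma, k) {
  if (any(k <= 0) || any(k > 1)) stop("k must be in (0, 1]")
  sigma * sqrt(2 * log(1 / k))
}

# symmetrised Gaussian-in-angle kernel evaluated at cos(theta) values
fiber_kernel <- function(cosang, sigma_rad) {
  ang <- acos(pmin(pmax(cosang, -1), 1))
  exp(-ang^2 / (2 * sigma_rad^2)) + exp(-(pi - ang)^2 / (2 * sigma_rad^2))
}

#' Generate a synthetic fiber phantom
#'
#' @param spec a [phantom_spec()].
#' @param mesh sphere mesh used to author the SH fODF volume (default a
#'   level-3 icosphere, 642 vertices).
#' @return a list of class `phantom` with fields `scalar`
#'   ([scalar_volume()] FA map), `peaks` ([peak_field()] with analytic
#'   directions and alphas), `sh` ([sh_volume()]), `truth` ([tractogram()]
#'   of centreline streamlines), `spec`, `mesh` and `affine`.
#' @export
make_phantom <- function(spec = phantom_spec(), mesh = make_icosphere(3L)) {
  vs <- spec$voxel_size
  aff <- affine(diag(c(vs, vs, vs, 1)))
  dims <- spec$shape
  centre <- (dims - 1) / 2 * vs
  nvox <- prod(dims)
  # world coordinates of every voxel centre (linear order: x fastest)
  idx <- arrayInd(seq_len(nvox), dims) - 1L
  wpts <- idx * vs
  sigma <- spec$kernel_sigma * pi / 180
  alpha <- analytic_alpha(spec$kernel_sigma, spec$fwhm_fraction) * pi / 180

  # per-bundle membership + local tangent
  bundles <- phantom_bundles(spec, centre, dims, vs, wpts)
  member <- vapply(bundles, `[[`, logical(nvox), "inside")
  member <- matrix(member, nvox, length(bundles))
  inside_any <- rowSums(member) > 0

  scalar <- array(spec$fa_outside, dims)
  scalar[inside_any] <- spec$fa_inside

  pk <- matrix(0, nvox, 20L)
  nslot <- integer(nvox)
  vals <- NULL
  ins_idx <- which(inside_any)
  if (length(ins_idx)) {
    vals <- matrix(0, length(ins_idx), nrow(mesh$vertices))
    for (b in seq_along(bundles)) {
      rows <- which(member[ins_idx, b])
      if (!length(rows)) next
      tang <- bundles[[b]]$tangent[ins_idx[rows], , drop = FALSE]
      ca <- tang %*% t(mesh$vertices)
      vals[rows, ] <- vals[rows, , drop = FALSE] + fiber_kernel(ca, sigma)
      vox <- ins_idx[rows]
      s <- nslot[vox]
      pk[cbind(vox, s * 4L + 1L)] <- tang[, 1L]
      pk[cbind(vox, s * 4L + 2L)] <- tang[, 2L]
      pk[cbind(vox, s * 4L + 3L)] <- tang[, 3L]
      pk[cbind(vox, s * 4L + 4L)] <- alpha
      nslot[vox] <- s + 1L
    }
  }

  sh <- matrix(0, nvox, n_sh_coeffs(spec$lmax))
  if (length(ins_idx)) {
    B <- cached_basis(mesh, spec$lmax)
    # one least-squares fit, many right-hand sides
    proj <- solve(crossprod(B), t(B))
    sh[ins_idx, ] <- vals %*% t(proj)
  }

  truth <- tractogram(lapply(bundles, `[[`, "centreline"), aff,
                      paste0("phantom geometry=", spec$geometry))
  structure(list(scalar = scalar_volume(scalar, aff),
                 peaks = peak_field(array(pk, c(dims, 20L)), aff, TRUE),
                 sh = sh_volume(array(sh, c(dims, n_sh_coeffs(spec$lmax))),
                                aff, spec$lmax),
                 truth = truth, spec = spec, mesh = mesh, affine = aff),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom '%s': %s voxels at %.2f mm, %d in-bundle>\n",
              x$spec$geometry, paste(x$spec$shape, collapse = " x "),
              x$spec$voxel_size, sum(x$scalar$data > x$spec$fa_outside)))
  invisible(x)
}

# bundle geometry: membership and per-voxel tangent over the full grid
phantom_bundles <- function(spec, centre, dims, vs, wpts) {
  r <- spec$bundle_radius
  nvox <- nrow(wpts)
  cyl <- function(axis_dir) {
    d <- sweep(wpts, 2L, centre)
    along <- drop(d %*% axis_dir)
    perp <- d - outer(along, axis_dir)
    inside <- sqrt(rowSums(perp^2)) <= r
    tangent <- matrix(rep(axis_dir, each = nvox), nvox, 3L)
    list(inside = inside, tangent = tangent)
  }
  extent <- (dims - 1) * vs
  line_pts <- function(p0, dir, lo, hi) {
    s <- seq(lo, hi, by = vs / 2)
    sweep(outer(s, dir), 2L, p0, `+`)
  }
  switch(spec$geometry,
    straight = {
      b <- cyl(c(1, 0, 0))
      b$centreline <- line_pts(c(0, centre[2L], centre[3L]), c(1, 0, 0),
                               0, extent[1L])
      list(b)
    },
    crossing = {
      psi <- spec$crossing_angle * pi / 180
      u2 <- c(cos(psi), sin(psi), 0)
      b1 <- cyl(c(1, 0, 0))
      b2 <- cyl(u2)
      half <- min(extent) / 2
      b1$centreline <- line_pts(c(0, centre[2L], centre[3L]), c(1, 0, 0),
                                0, extent[1L])
      b2$centreline <- sweep(outer(seq(-half, half, by = vs / 2), u2), 2L,
                             centre, `+`)
      list(b1, b2)
    },
    curved = {
      R <- spec$curve_radius
      O <- centre - c(R * cos(pi / 4), R * sin(pi / 4), 0)
      # the tube occupies only the first quadrant about O (theta in [0, 90])
      if (any(O[1:2] + (R + r) > extent[1:2]) || any(O[1:2] < 0) ||
          centre[3L] + r > extent[3L] || centre[3L] - r < 0)
        stop("curved bundle does not fit inside the volume; ",
             "reduce curve_radius or bundle_radius")
      d <- sweep(wpts, 2L, c(O[1L], O[2L], 0))
      rho <- sqrt(d[, 1L]^2 + d[, 2L]^2)
      theta <- atan2(d[, 2L], d[, 1L])
      inside <- abs(rho - R) <= r & abs(wpts[, 3L] - centre[3L]) <= r &
                theta >= 0 & theta <= pi / 2
      tangent <- cbind(-sin(theta), cos(theta), 0)
      th <- seq(0, pi / 2, length.out = ceiling(R * pi / 2 / (vs / 2)) + 1L)
      centreline <- cbind(O[1L] + R * cos(th), O[2L] + R * sin(th), centre[3L])
      list(list(inside = inside, tangent = tangent, centreline = centreline))
    })
}
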