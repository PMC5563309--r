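# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

shared_mesh <- function(subdivisions = 3L) {
  key <- paste0("mesh", subdivisions)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_icosphere(subdivisions)
  .fixtures[[key]]
}

shared_phantom <- function(geometry = "straight", fwhm_fraction = 0.35,
                           fa_inside = 0.8) {
  key <- paste(geometry, fwhm_fraction, fa_inside, sep = "_")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_phantom(
      phantom_spec(geometry = geometry, fwhm_fraction = fwhm_fraction,
                   fa_inside = fa_inside),
      mesh = shared_mesh())
  }
  .fixtures[[key]]
}

phantom_centre <- function(ph) (ph$spec$shape - 1) / 2 * ph$spec$voxel_size

centre_box <- function(ph, half_voxels = 1) {
  seed_box(phantom_centre(ph), rep(half_voxels * ph$spec$voxel_size, 3L))
}

# Gaussian angular profile about +z, symmetrised, as a spherical function
gaussian_profile <- function(mesh, sigma_deg = 20, axis = c(0, 0, 1)) {
  s <- sigma_deg * pi / 180
  ca <- drop(mesh$vertices %*% axis)
  ang <- acos(pmin(pmax(ca, -1), 1))
  spherical_function(exp(-ang^2 / (2 * s^2)) + exp(-(pi - ang)^2 / (2 * s^2)),
                     mesh)
}

# per-step turning angles (degrees) of one streamline
turning_angles <- function(s) {
  d <- diff(s)
  d <- d / sqrt(rowSums(d^2))
  if (nrow(d) < 2L) return(numeric())
  dots <- rowSums(d[-1L, , drop = FALSE] * d[-nrow(d), , drop = FALSE])
  acos(pmin(pmax(dots, -1), 1)) * 180 / pi
}

# random tractogram of short random-walk streamlines inside a cube
random_tractogram <- function(n_streamlines, n_points = 20L, extent = 60,
                              seed = 1L) {
  set.seed(seed)
  sl <- lapply(seq_len(n_streamlines), function(i) {
    start <- runif(3, 5, extent - 5)
    steps <- matrix(rnorm(3 * (n_points - 1L), sd = 0.8), n_points - 1L, 3L)
    apply(rbind(start, steps), 2L, cumsum)
  })
  tractogram(sl, affine(diag(c(1.72, 1.72, 1.72, 1))))
}

expect_unit_rows <- function(m, tol = 1e-9) {
  expect_lt(max(abs(sqrt(rowSums(m^2)) - 1)), tol)
}
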