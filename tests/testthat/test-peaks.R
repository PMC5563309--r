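test_that("peak finding recovers crossing-fiber geometry and honours limits", {
  m <- shared_mesh()
  # two fibers at 90 degrees
  two <- spherical_function(
    gaussian_profile(m, 20, c(1, 0, 0))$values +
    gaussian_profile(m, 20, c(0, 1, 0))$values, m)
  pk <- find_peaks_on_sphere(two)
  expect_equal(nrow(pk), 2L)
  dirs <- as.matrix(pk[, c("x", "y", "z")])
  err_to <- function(axis) min(acos(pmin(abs(dirs %*% axis), 1)))
  expect_lt(err_to(c(1, 0, 0)), m$max_edge)
  expect_lt(err_to(c(0, 1, 0)), m$max_edge)
  ang <- acos(min(abs(sum(dirs[1, ] * dirs[2, ])), 1)) * 180 / pi
  expect_gt(ang, 90 - m$max_edge * 180 / pi)

  # isotropic function: no strict local maximum, so no peaks
  iso <- spherical_function(rep(1, nrow(m$vertices)), m)
  expect_equal(nrow(find_peaks_on_sphere(iso)), 0L)

  # max_peaks cap on a 5-lobe function (axes from icosahedron directions)
  m0 <- make_icosphere(0)
  axes <- m0$vertices[seq_len(12) <= m0$antipode, , drop = FALSE][1:5, ]
  vals <- rowSums(vapply(seq_len(5), function(i) {
    gaussian_profile(m, 10, axes[i, ])$values
  }, numeric(nrow(m$vertices))))
  five <- spherical_function(vals, m)
  p5 <- find_peaks_on_sphere(five, peak_extraction_params(
    relative_threshold = 0.3, min_separation_angle = 15, max_peaks = 5))
  expect_equal(nrow(p5), 5L)
  p3 <- find_peaks_on_sphere(five, peak_extraction_params(
    relative_threshold = 0.3, min_separation_angle = 15, max_peaks = 3))
  expect_equal(nrow(p3), 3L)

  # relative threshold drops minor lobes
  uneven <- spherical_function(
    gaussian_profile(m, 15, c(1, 0, 0))$values +
    0.4 * gaussian_profile(m, 15, c(0, 0, 1))$values, m)
  expect_equal(nrow(find_peaks_on_sphere(
    uneven, peak_extraction_params(relative_threshold = 0.5))), 1L)
})

test_that("peak finding equals a brute-force neighbour-scan oracle", {
  m <- shared_mesh()
  params <- peak_extraction_params(relative_threshold = 0.4,
                                   min_separation_angle = 20, max_peaks = 5)
  brute <- function(f) {
    vals <- f$values
    cand <- which(vapply(seq_along(vals), function(i) {
      nb <- vals[m$adjacency[[i]]]
      all(vals[i] >= nb) && any(vals[i] > nb)
    }, logical(1)))
    cand <- cand[vals[cand] >= params$relative_threshold * max(vals)]
    cand <- cand[order(vals[cand], decreasing = TRUE)]
    kept <- integer()
    for (i in cand) {
      if (length(kept) >= params$max_peaks) break
      ok <- TRUE
      for (j in kept) {
        a <- acos(min(abs(sum(m$vertices[i, ] * m$vertices[j, ])), 1)) * 180 / pi
        if (a < params$min_separation_angle) ok <- FALSE
      }
      if (ok) kept <- c(kept, i)
    }
    kept
  }
  set.seed(21)
  for (r in 1:8) {
    f <- evaluate_fodf(rnorm(45), m)
    f <- spherical_function(f$values - min(f$values), m)
    expect_identical(find_peaks_on_sphere(f, params)$vertex, brute(f))
  }
})

test_that("uncertainty angle matches the analytic Gaussian width", {
  m <- shared_mesh()
  f <- gaussian_profile(m, 20)
  pk <- find_peaks_on_sphere(f)$vertex[1]
  edge_deg <- m$max_edge * 180 / pi
  prev <- -Inf
  for (k in c(0.95, 0.75, 0.5, 0.35, 0.15)) {
    a <- uncertainty_angle(f, pk, k) * 180 / pi
    expect_lt(abs(a - analytic_alpha(20, k)), edge_deg)
    expect_gte(a, prev - 1e-12)  # smaller fraction k, wider cone
    prev <- a
  }
  # k = 1: the first strictly-lower vertex is a nearest neighbour
  a1 <- uncertainty_angle(f, pk, 1)
  nb <- m$adjacency[[pk]]
  nb_ang <- acos(pmin(abs(drop(m$vertices[nb, ] %*% m$vertices[pk, ])), 1))
  expect_lte(a1, max(nb_ang) + 1e-9)

  # constant function never drops below the fraction: capped at pi/2
  const <- spherical_function(rep(1, nrow(m$vertices)), m)
  expect_equal(uncertainty_angle(const, 1L, 0.5), pi / 2)
  expect_error(uncertainty_angle(f, pk, 0), "0, 1")
  expect_error(uncertainty_angle(f, pk, 1.2), "0, 1")
})

test_that("alpha ordering: wider cones at smaller fractions, per monotone profile", {
  m <- shared_mesh()
  prev <- -Inf
  f <- gaussian_profile(m, 25)
  pk <- find_peaks_on_sphere(f)$vertex[1]
  for (k in c(0.95, 0.75, 0.35)) {
    a <- uncertainty_angle(f, pk, k)
    expect_gte(a, prev)   # nested cones: alpha(0.95) <= alpha(0.75) <= alpha(0.35)
    prev <- a
  }
})

test_that("peaks_from_sh_volume recovers the phantom peak field", {
  ph <- shared_phantom("straight")
  pf <- peaks_from_sh_volume(ph$sh, ph$mesh,
                             peak_extraction_params(fwhm_fraction = 0.35),
                             mask = ph$scalar, mask_threshold = 0.1)
  expect_true(pf$has_alpha)
  dims <- ph$spec$shape
  nvox <- prod(dims)
  truth <- matrix(ph$peaks$data, nvox)
  got <- matrix(pf$data, nvox)
  inside <- rowSums(abs(truth)) > 0
  # masked-out voxels stay all-zero
  expect_true(all(got[!inside, ] == 0))
  # every in-mask voxel: exactly one peak within a mesh edge of (1,0,0)
  n_peaks <- rowSums(matrix(got[inside, c(1, 5, 9, 13, 17)] != 0 |
                            got[inside, c(2, 6, 10, 14, 18)] != 0 |
                            got[inside, c(3, 7, 11, 15, 19)] != 0,
                            ncol = 5))
  expect_true(all(n_peaks == 1))
  dots <- abs(got[inside, 1])
  expect_lt(max(acos(pmin(dots, 1))), ph$mesh$max_edge)

  # alpha shrinks as the fraction grows, voxel-wise
  pf95 <- peaks_from_sh_volume(ph$sh, ph$mesh,
                               peak_extraction_params(fwhm_fraction = 0.95),
                               mask = ph$scalar, mask_threshold = 0.1)
  a35 <- matrix(pf$data, nvox)[inside, 4]
  a95 <- matrix(pf95$data, nvox)[inside, 4]
  expect_true(all(a95 <= a35 + 1e-12))

  # empty mask: all-zero field
  zero_mask <- scalar_volume(array(0, dims), ph$affine)
  pf0 <- peaks_from_sh_volume(ph$sh, ph$mesh, mask = zero_mask,
                              mask_threshold = 0.1)
  expect_true(all(pf0$data == 0))
})
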