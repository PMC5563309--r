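test_that("seed sampling is uniform in the box and reproducible", {
  box <- seed_box(c(10, 20, 30), c(2, 3, 4))
  s1 <- sample_seeds(box, 1000, rng_seed = 9)
  s2 <- sample_seeds(box, 1000, rng_seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1000L)  # 10 seeds per axis = 10^3 seeds
  lo <- box$center - box$half_extents
  hi <- box$center + box$half_extents
  for (d in 1:3) {
    expect_true(all(s1[, d] >= lo[d] & s1[, d] <= hi[d]))
  }
  expect_false(identical(s1, sample_seeds(box, 1000, rng_seed = 10)))
})

test_that("select_peak resolves signs, takes the closest axis and gates the angle", {
  # axial symmetry: an antiparallel peak is followed via its sign flip
  r <- select_peak(c(-1, 0, 0), rbind(c(1, 0, 0)))
  expect_equal(r$direction, c(-1, 0, 0))
  expect_equal(r$angle, 0)

  prev <- c(0.9, 0.1, 0); prev <- prev / sqrt(sum(prev^2))
  r <- select_peak(prev, rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(r$direction, c(1, 0, 0))
  expect_equal(r$index, 1L)

  # 60-degree peak is rejected under a 50-degree gate
  p60 <- c(cos(60 * pi / 180), sin(60 * pi / 180), 0)
  expect_null(select_peak(c(1, 0, 0), rbind(p60), max_angle = 50))
  expect_false(is.null(select_peak(c(1, 0, 0), rbind(p60), max_angle = 70)))

  # no nonzero peak slots signal termination
  expect_null(select_peak(c(1, 0, 0), matrix(0, 5, 3)))

  # alpha of the winning peak is carried through
  r <- select_peak(c(1, 0, 0), rbind(c(0, 0, 1), c(1, 0, 0)),
                   alpha = c(0.1, 0.5))
  expect_equal(r$alpha, 0.5)
})

test_that("cone sampling is uniform on the spherical cap", {
  v <- c(1, 1, 1) / sqrt(3)
  expect_identical(cone_sample(v, 0, u = c(0.3, 0.8)), v)   # degenerate cone
  expect_error(cone_sample(v, 2), "alpha")

  set.seed(123)
  alpha <- 30 * pi / 180
  n <- 20000
  d <- t(vapply(seq_len(n), function(i) cone_sample(v, alpha), numeric(3)))
  expect_unit_rows(d, tol = 1e-9)
  dots <- drop(d %*% v)
  expect_true(all(dots >= cos(alpha) - 1e-12))
  # mean of U(cos a, 1) with 3-sigma band
  se <- (1 - cos(alpha)) / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(dots) - (1 + cos(alpha)) / 2), 3 * se)
})

test_that("the deterministic direction update matches its closed form and limits", {
  vp <- c(0, 1, 0); vn <- c(1, 0, 0)
  expect_equal(advance_deterministic(vp, vn, f = 1, g = 0.7), vn)
  expect_equal(advance_deterministic(vp, vn, f = 0, g = 1), vn)
  expect_equal(advance_deterministic(vp, vn, f = 0, g = 0), vp)

  got <- advance_deterministic(vp, vn, f = 0.5, g = 0.2)
  expect_equal(got, c(0.6, 0.4, 0) / sqrt(0.52), tolerance = 1e-12)

  # f outside [0,1] is clipped
  expect_equal(advance_deterministic(vp, vn, f = 1.7, g = 0.2), vn)

  # exact antiparallel cancellation signals termination
  expect_equal(advance_deterministic(c(-1, 0, 0), c(1, 0, 0), f = 0.5, g = 0),
               c(0, 0, 0))
})

test_that("the probabilistic update reuses one cone draw and has the alpha=0 limit", {
  vp <- c(0, 1, 0); vn <- c(1, 0, 0)
  u <- c(0.42, 0.77)
  for (f in c(0, 0.3, 1)) {
    expect_equal(advance_probabilistic(vp, vn, alpha_n = 0, f = f, g = 0.2, u = u),
                 advance_deterministic(vp, vn, f = f, g = 0.2))
  }
  # f = 1: the step is exactly the cone draw
  w <- cone_sample(vn, 0.4, u = u)
  expect_equal(advance_probabilistic(vp, vn, alpha_n = 0.4, f = 1, g = 0.2, u = u), w)
  # reproducible given the same uniforms
  expect_identical(advance_probabilistic(vp, vn, 0.3, 0.5, 0.2, u = u),
                   advance_probabilistic(vp, vn, 0.3, 0.5, 0.2, u = u))
})

test_that("single-streamline tracking crosses a uniform straight phantom", {
  ph <- shared_phantom("straight", fa_inside = 1)  # f = 1: pure peak following
  centre <- phantom_centre(ph)
  res <- track_streamline(centre, ph$peaks, ph$scalar,
                          tracking_params(rng_seed = 3))
  expect_equal(res$reason, "emitted")
  s <- res$streamline
  spacing <- sqrt(rowSums(diff(s)^2))
  expect_lt(max(abs(spacing - 0.5)), 1e-9)
  expect_lt(max(abs(s[, 2] - centre[2])), 1e-9)  # never leaves the x line
  expect_lt(max(abs(s[, 3] - centre[3])), 1e-9)
  # spans the whole 40-voxel (68.8 mm) volume
  expect_gt(max(s[, 1]) - min(s[, 1]), 60)

  # a seed in a peak-free voxel is rejected
  corner <- voxel_to_world(c(1, 1, 1), ph$affine)
  res0 <- track_streamline(corner, ph$peaks, ph$scalar, tracking_params())
  expect_equal(res0$reason, "no-initial-peak")
  expect_null(res0$streamline)

  expect_error(track_streamline(c(-50, 0, 0), ph$peaks, ph$scalar,
                                tracking_params()), "outside")
})

test_that("a mask island narrower than min_length rejects as too short", {
  a <- affine(diag(c(1, 1, 1, 1)))
  dims <- c(20L, 9L, 9L)
  mask <- array(0, dims)
  mask[9:12, 5, 5] <- 1          # 4 mm wide corridor
  pk <- array(0, c(dims, 20))
  pk[9:12, 5, 5, 1] <- 1         # single +x peak
  field <- peak_field(pk, a)
  res <- track_streamline(c(10, 4, 4), field, scalar_volume(mask, a),
                          tracking_params(step_size = 0.5, min_length = 10))
  expect_equal(res$reason, "too-short")
})

test_that("bundle tracking obeys its contracts on the straight phantom", {
  ph <- shared_phantom("straight")
  res <- track_bundle(centre_box(ph), ph$peaks, ph$scalar,
                      tracking_params(rng_seed = 11), n_seeds = 200)
  expect_equal(sum(res$tally$n), 200L)                 # emitted + rejected = seeds
  expect_length(res$tractogram$streamlines, 200L)      # all emitted here
  lens <- streamline_lengths(res$tractogram)
  expect_true(all(lens >= 10 & lens <= 200))
  # near-identical straight lines: all x-aligned
  for (s in res$tractogram$streamlines[1:20]) {
    expect_lt(max(turning_angles(s)), 1e-6)
  }
  expect_match(res$tractogram$provenance, "mode=deterministic")
  expect_match(res$tractogram$provenance, "rng=11")
})

test_that("bundle and single-streamline tracking agree stream-for-stream", {
  ph <- shared_phantom("crossing")
  params <- tracking_params(mode = "probabilistic", rng_seed = 17)
  box <- centre_box(ph)
  res <- track_bundle(box, ph$peaks, ph$scalar, params, n_seeds = 12)
  streams <- conetrack:::rng_streams(params$rng_seed, 12)
  for (i in c(1L, 5L, 12L)) {
    single <- track_streamline(res$seeds[i, ], ph$peaks, ph$scalar, params,
                               stream = streams[[i + 1L]])
    expect_identical(single$reason, res$status[i])
    if (single$reason == "emitted") {
      j <- sum(res$status[seq_len(i)] == "emitted")
      expect_identical(single$streamline, res$tractogram$streamlines[[j]])
    }
  }
})

test_that("probabilistic tracking is reproducible and respects the angle gate", {
  ph <- shared_phantom("crossing")
  params <- tracking_params(mode = "probabilistic", rng_seed = 23)
  r1 <- track_bundle(centre_box(ph), ph$peaks, ph$scalar, params, n_seeds = 150)
  r2 <- track_bundle(centre_box(ph), ph$peaks, ph$scalar, params, n_seeds = 150)
  expect_identical(r1$tractogram$streamlines, r2$tractogram$streamlines)
  turns <- unlist(lapply(r1$tractogram$streamlines, turning_angles))
  expect_true(all(turns <= params$max_angle + 1e-9))
  expect_gt(max(turns), 1)  # actually probabilistic
})

test_that("stricter angle gates shorten bundles on the curved phantom", {
  ph <- shared_phantom("curved")
  box <- centre_box(ph)
  counts <- c(); mean_len <- c()
  for (ang in c(50, 6, 3, 1)) {
    res <- track_bundle(box, ph$peaks, ph$scalar,
                        tracking_params(max_angle = ang, min_length = 1,
                                        rng_seed = 31),
                        n_seeds = 100)
    counts <- c(counts, length(res$tractogram$streamlines))
    mean_len <- c(mean_len, mean(streamline_lengths(res$tractogram)))
  }
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(mean_len) <= 1e-9))
})

test_that("a box fully outside the volume is refused", {
  ph <- shared_phantom("straight")
  far <- seed_box(c(500, 500, 500), c(2, 2, 2))
  expect_error(track_bundle(far, ph$peaks, ph$scalar, tracking_params()),
               "outside")
})
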