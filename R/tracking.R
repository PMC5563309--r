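#' Tracking parameters
#'
#' Defaults are the demonstrated operating point of the real-time
#' tractography method this package implements: maximum turning angle 50
#' degrees, streamline length 10-200 mm, mask (FA) threshold 0.1, step size
#' 0.5 mm, 10 seeds per axis (1000 seeds) and puncture g = 0.2.
#'
#' @param step_size distance advanced per step, mm.
#' @param max_angle maximum angle between consecutive propagation
#'   directions, degrees, in (0, 90].
#' @param mask_threshold minimum mask value for tracking to continue.
#' @param puncture g in `[0, 1]`: weight of the newly selected direction
#'   against the incoming one in the direction update.
#' @param min_length,max_length valid streamline arc-length range, mm.
#' @param seeds_per_axis s; a bundle run draws s^3 random seeds.
#' @param mode `"deterministic"` or `"probabilistic"` (cone-of-uncertainty
#'   sampling; requires a peak field with alphas).
#' @param rng_seed master seed; every streamline gets its own independent
#'   substream, so results are order-independent.
#' @return a list of class `tracking_params`.
#' @export
tracking_params <- function(step_size = 0.5, max_angle = 50,
                            mask_threshold = 0.1, puncture = 0.2,
                            min_length = 10, max_length = 200,
                            seeds_per_axis = 10L,
                            mode = c("deterministic", "probabilistic"),
                            rng_seed = 42L) {
  mode <- match.arg(mode)
  stopifnot(step_size > 0, max_angle > 0, max_angle <= 90,
            puncture >= 0, puncture <= 1,
            min_length > 0, min_length < max_length,
            seeds_per_axis >= 1L)
  structure(list(step_size = step_size, max_angle = max_angle,
                 mask_threshold = mask_threshold, puncture = puncture,
                 min_length = min_length, max_length = max_length,
                 seeds_per_axis = as.integer(seeds_per_axis), mode = mode,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' Axis-aligned seed/selection boxes
#'
#' @param center box centre, world mm (length 3).
#' @param half_extents half side lengths, mm (length 3, all > 0).
#' @return a list of class `seed_box`.
#' @export
seed_box <- function(center, half_extents) {
  stopifnot(length(center) == 3L, length(half_extents) == 3L,
            all(half_extents > 0))
  structure(list(center = as.numeric(center),
                 half_extents = as.numeric(half_extents)),
            class = "seed_box")
}

# ---- RNG substreams --------------------------------------------------------
# One L'Ecuyer-CMRG stream per streamline (stream 1 is reserved for seed
# placement), so per-streamline results do not depend on evaluation order.

rng_streams <- function(master_seed, n) {
  old_kind <- RNGkind()
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(master_seed %% 2147483647L))
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n + 1L)
  for (i in seq_len(n + 1L)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

stream_runif <- function(stream, m) {
  old_kind <- RNGkind()
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  assign(".Random.seed", stream, envir = globalenv())
  stats::runif(m)
}

#' Draw seed positions uniformly inside a box
#'
#' @param box a [seed_box()].
#' @param n number of seeds.
#' @param rng_seed integer seed (ignored when `stream` is given).
#' @param stream internal: a pre-built RNG substream.
#' @return an n x 3 matrix of world-mm positions.
#' @export
sample_seeds <- function(box, n, rng_seed = 42L, stream = NULL) {
  stopifnot(n >= 1L)
  if (is.null(stream)) stream <- rng_streams(rng_seed, 0L)[[1L]]
  u <- matrix(stream_runif(stream, 3L * n), n, 3L)
  sweep(sweep(u * 2 - 1, 2L, box$half_extents, `*`), 2L, box$center, `+`)
}

# ---- single-step operations ------------------------------------------------

#' Select the voxel peak closest in angle to the current direction
#'
#' Peaks are axially symmetric (+/-p equivalent), so both signs of every
#' nonzero peak are considered and the sign-resolved direction maximising the
#' dot product with `prev_dir` is returned. Exact ties go to the lowest peak
#' index. Returns `NULL` — a termination signal — when no nonzero peak
#' exists or the winning angle exceeds `max_angle`.
#'
#' @param prev_dir unit length-3 vector, the current tracking direction.
#' @param peaks m x 3 matrix of peak directions (rows may be zero = absent).
#' @param alpha optional length-m vector of uncertainty half-angles
#'   (radians) carried through to the result.
#' @param max_angle gate angle, degrees.
#' @return `NULL`, or a list with `direction` (sign-resolved unit vector),
#'   `alpha`, `angle` (degrees) and `index`.
#' @export
select_peak <- function(prev_dir, peaks, alpha = NULL, max_angle = 90) {
  peaks <- matrix(peaks, ncol = 3L)
  nz <- rowSums(abs(peaks)) > 0
  if (!any(nz)) return(NULL)
  dots <- drop(peaks %*% prev_dir)
  adots <- ifelse(nz, abs(dots), -Inf)
  i <- which.max(adots)  # first max wins on ties
  if (adots[i] < cos(max_angle * pi / 180) - 1e-12) return(NULL)
  sgn <- if (dots[i] >= 0) 1 else -1
  list(direction = sgn * peaks[i, ],
       alpha = if (is.null(alpha)) 0 else alpha[i],
       angle = acos(min(max(adots[i], -1), 1)) * 180 / pi,
       index = i)
}

#' Sample a direction uniformly inside a cone of uncertainty
#'
#' Draws a direction uniform over the spherical cap of half-angle `alpha`
#' about `v`; `alpha = 0` returns `v` exactly, which makes probabilistic
#' tracking collapse onto the deterministic propagation.
#'
#' @param v unit axis of the cone.
#' @param alpha half-angle, radians, in `[0, pi/2]`.
#' @param u optional two uniforms in `[0, 1]` (height and azimuth); drawn
#'   from the current RNG when `NULL`.
#' @return a unit length-3 vector `d` with `dot(d, v) >= cos(alpha)`.
#' @export
cone_sample <- function(v, alpha, u = NULL) {
  if (alpha < 0 || alpha > pi / 2 + 1e-12) stop("alpha must be in [0, pi/2]")
  if (is.null(u)) u <- stats::runif(2L)
  drop(cone_sample_rows(matrix(v, 1L, 3L), alpha, u[1L], u[2L]))
}

# vectorised core: one cap draw per row of V
cone_sample_rows <- function(V, alpha, u1, u2) {
  z <- cos(alpha) + u1 * (1 - cos(alpha))
  st <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * u2
  # orthonormal frame per row: helper axis away from V
  use_x <- abs(V[, 1L]) < 0.9
  e <- cbind(ifelse(use_x, 1, 0), ifelse(use_x, 0, 1), 0)
  u <- cbind(e[, 2L] * V[, 3L] - e[, 3L] * V[, 2L],
             e[, 3L] * V[, 1L] - e[, 1L] * V[, 3L],
             e[, 1L] * V[, 2L] - e[, 2L] * V[, 1L])
  u <- u / sqrt(rowSums(u^2))
  w <- cbind(V[, 2L] * u[, 3L] - V[, 3L] * u[, 2L],
             V[, 3L] * u[, 1L] - V[, 1L] * u[, 3L],
             V[, 1L] * u[, 2L] - V[, 2L] * u[, 1L])
  (st * cos(phi)) * u + (st * sin(phi)) * w + z * V
}

#' Deterministic and probabilistic direction updates
#'
#' The deterministic update blends the incoming direction `V(n-1)` with the
#' selected peak `V(n)` under the local scalar weight `f` (FA/GFA, clipped
#' to `[0, 1]`) and the puncture `g`:
#' `V(n+1) = normalize(f V(n) + (1 - f)((1 - g) V(n-1) + g V(n)))`.
#' The probabilistic update replaces `V(n)` by one cone sample
#' `W = theta(V(n), alpha)` — drawn once and reused in both terms:
#' `V(n+1) = normalize(f W + (1 - f)((1 - g) V(n-1) + g W))`.
#' A zero blend (exact antiparallel cancellation) returns `c(0, 0, 0)`,
#' signalling termination.
#'
#' @param v_prev,v_n unit length-3 vectors: incoming and selected direction.
#' @param f local scalar weight; clipped to `[0, 1]`.
#' @param g puncture in `[0, 1]`.
#' @param alpha_n uncertainty half-angle of the selected peak, radians.
#' @param u optional two uniforms for the cone draw (see [cone_sample()]).
#' @return a unit length-3 vector, or `c(0, 0, 0)` on degeneracy.
#' @export
advance_deterministic <- function(v_prev, v_n, f, g) {
  f <- min(max(f, 0), 1)
  v <- f * v_n + (1 - f) * ((1 - g) * v_prev + g * v_n)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(0, 0, 0))
  v / n
}

#' @rdname advance_deterministic
#' @export
advance_probabilistic <- function(v_prev, v_n, alpha_n, f, g, u = NULL) {
  w <- cone_sample(v_n, alpha_n, u)
  advance_deterministic(v_prev, w, f, g)
}

# ---- the tracking engine ---------------------------------------------------
# Vectorised across streamlines: one loop over steps, matrix ops over the
# rows still active. Each streamline consumes uniforms only from its own
# pre-drawn substream row, so single- and bundle-tracking agree exactly.

peak_matrix <- function(peaks) {
  matrix(peaks$data, nrow = prod(dim(peaks$data)[1:3]))
}

# propagate one half-track for all rows; returns appended points + stop info
propagate_half <- function(pos, dir, budget, engine, U, ucnt) {
  n <- nrow(pos)
  maxsteps <- max(budget, 0L)
  ptsX <- matrix(NA_real_, n, maxsteps)
  ptsY <- matrix(NA_real_, n, maxsteps)
  ptsZ <- matrix(NA_real_, n, maxsteps)
  npts <- integer(n)
  reason <- rep(NA_character_, n)
  active <- budget > 0L & rowSums(abs(dir)) > 0
  reason[!active] <- "max-length"
  p <- engine$params
  cos_gate <- cos(p$max_angle * pi / 180)
  t <- 0L
  while (any(active)) {
    t <- t + 1L
    rows <- which(active)
    vox <- round(apply_affine(pos[rows, , drop = FALSE], engine$ainv))
    oob <- vox[, 1L] < 0 | vox[, 1L] > engine$dims[1L] - 1L |
           vox[, 2L] < 0 | vox[, 2L] > engine$dims[2L] - 1L |
           vox[, 3L] < 0 | vox[, 3L] > engine$dims[3L] - 1L
    if (any(oob)) {
      reason[rows[oob]] <- "left-volume"
      active[rows[oob]] <- FALSE
      rows <- rows[!oob]
      vox <- vox[!oob, , drop = FALSE]
      if (!length(rows)) break
    }
    lin <- 1L + vox[, 1L] + engine$dims[1L] * (vox[, 2L] + engine$dims[2L] * vox[, 3L])
    maskv <- engine$maskvec[lin]
    low <- maskv < p$mask_threshold
    if (any(low)) {
      reason[rows[low]] <- "mask"
      active[rows[low]] <- FALSE
      rows <- rows[!low]
      lin <- lin[!low]
      maskv <- maskv[!low]
      if (!length(rows)) break
    }
    f <- pmin(pmax(maskv, 0), 1)
    prev <- dir[rows, , drop = FALSE]
    # best peak over slots and signs
    best_adot <- rep(-Inf, length(rows))
    best_dot <- numeric(length(rows))
    best_slot <- integer(length(rows))
    for (s in 0:4) {
      cols <- s * engine$stride + 1:3
      px <- engine$peakmat[lin, cols, drop = FALSE]
      nz <- rowSums(abs(px)) > 0
      d <- rowSums(px * prev)
      ad <- ifelse(nz, abs(d), -Inf)
      upd <- ad > best_adot
      best_adot[upd] <- ad[upd]
      best_dot[upd] <- d[upd]
      best_slot[upd] <- s
    }
    fail <- !is.finite(best_adot) | best_adot < cos_gate - 1e-12
    if (any(fail)) {
      reason[rows[fail]] <- ifelse(is.finite(best_adot[fail]), "angle", "no-peak")
      active[rows[fail]] <- FALSE
      keep <- !fail
      rows <- rows[keep]; lin <- lin[keep]; f <- f[keep]
      prev <- prev[keep, , drop = FALSE]
      best_dot <- best_dot[keep]; best_slot <- best_slot[keep]
      if (!length(rows)) break
    }
    sgn <- ifelse(best_dot >= 0, 1, -1)
    ccols <- outer(best_slot * engine$stride, 1:3, `+`)
    peakdir <- sgn * cbind(engine$peakmat[cbind(lin, ccols[, 1L])],
                           engine$peakmat[cbind(lin, ccols[, 2L])],
                           engine$peakmat[cbind(lin, ccols[, 3L])])
    if (p$mode == "probabilistic") {
      alpha <- if (engine$has_alpha)
        engine$peakmat[cbind(lin, best_slot * 4L + 4L)] else rep(0, length(rows))
      u1 <- U[cbind(rows, ucnt[rows] + 1L)]
      u2 <- U[cbind(rows, ucnt[rows] + 2L)]
      ucnt[rows] <- ucnt[rows] + 2L
      W <- cone_sample_rows(peakdir, alpha, u1, u2)
      wdot <- rowSums(W * prev)
      bad <- wdot < cos_gate - 1e-12
      if (any(bad)) {
        reason[rows[bad]] <- "angle"
        active[rows[bad]] <- FALSE
        keep <- !bad
        rows <- rows[keep]; f <- f[keep]
        prev <- prev[keep, , drop = FALSE]
        W <- W[keep, , drop = FALSE]
        if (!length(rows)) break
      }
    } else {
      W <- peakdir
    }
    a <- f + (1 - f) * p$puncture
    vnew <- a * W + ((1 - f) * (1 - p$puncture)) * prev
    nrm <- sqrt(rowSums(vnew^2))
    dead <- nrm < 1e-12
    if (any(dead)) {
      reason[rows[dead]] <- "degenerate"
      active[rows[dead]] <- FALSE
      keep <- !dead
      rows <- rows[keep]; vnew <- vnew[keep, , drop = FALSE]; nrm <- nrm[keep]
      if (!length(rows)) break
    }
    vnew <- vnew / nrm
    newpos <- pos[rows, , drop = FALSE] + p$step_size * vnew
    pos[rows, ] <- newpos
    dir[rows, ] <- vnew
    npts[rows] <- npts[rows] + 1L
    ptsX[cbind(rows, npts[rows])] <- newpos[, 1L]
    ptsY[cbind(rows, npts[rows])] <- newpos[, 2L]
    ptsZ[cbind(rows, npts[rows])] <- newpos[, 3L]
    done <- npts[rows] >= budget[rows]
    if (any(done)) {
      reason[rows[done]] <- "max-length"
      active[rows[done]] <- FALSE
    }
  }
  list(ptsX = ptsX, ptsY = ptsY, ptsZ = ptsZ, npts = npts,
       reason = reason, ucnt = ucnt)
}

track_engine <- function(seeds, peaks, mask, params, streams) {
  dims <- dim(peaks$data)[1:3]
  if (!all(dim(mask$data) == dims))
    stop("mask grid does not match the peak field")
  n <- nrow(seeds)
  engine <- list(params = params,
                 dims = dims,
                 ainv = solve(unclass(peaks$affine)),
                 maskvec = as.vector(mask$data),
                 peakmat = peak_matrix(peaks),
                 stride = if (peaks$has_alpha) 4L else 3L,
                 has_alpha = peaks$has_alpha)
  if (params$mode == "probabilistic" && !peaks$has_alpha)
    warning("probabilistic mode on a peak field without alphas: cones collapse to alpha = 0")
  max_steps <- as.integer(floor(params$max_length / params$step_size))
  n_u <- 1L + 2L * (max_steps + 4L)
  U <- matrix(0, n, n_u)
  for (i in seq_len(n)) U[i, ] <- stream_runif(streams[[i + 1L]], n_u)
  ucnt <- rep(1L, n)  # column 1 = initial-peak draw

  # initial peak: a uniformly random nonzero peak of the seed's voxel
  svox <- round(apply_affine(seeds, engine$ainv))
  in_vol <- svox[, 1L] >= 0 & svox[, 1L] <= dims[1L] - 1L &
            svox[, 2L] >= 0 & svox[, 2L] <= dims[2L] - 1L &
            svox[, 3L] >= 0 & svox[, 3L] <= dims[3L] - 1L
  init_dir <- matrix(0, n, 3L)
  status <- rep("ok", n)
  status[!in_vol] <- "seed-outside-volume"
  iv <- which(in_vol)
  if (length(iv)) {
    lin <- 1L + svox[iv, 1L] + dims[1L] * (svox[iv, 2L] + dims[2L] * svox[iv, 3L])
    nzcount <- integer(length(iv))
    nzmask <- matrix(FALSE, length(iv), 5L)
    for (s in 0:4) {
      cols <- s * engine$stride + 1:3
      nzmask[, s + 1L] <- rowSums(abs(engine$peakmat[lin, cols, drop = FALSE])) > 0
    }
    nzcount <- rowSums(nzmask)
    none <- nzcount == 0L
    status[iv[none]] <- "no-initial-peak"
    ok <- which(!none)
    if (length(ok)) {
      pick <- floor(U[cbind(iv[ok], 1L)] * nzcount[ok]) + 1L
      pick <- pmin(pick, nzcount[ok])
      # map the pick-th nonzero slot to its slot index
      slot <- integer(length(ok))
      cum <- matrix(t(apply(nzmask[ok, , drop = FALSE], 1L, cumsum)), length(ok), 5L)
      for (s in 1:5) slot[cum[, s] == pick & nzmask[ok, s]] <- s - 1L
      ccols <- outer(slot * engine$stride, 1:3, `+`)
      linok <- lin[ok]
      init_dir[iv[ok], ] <- cbind(engine$peakmat[cbind(linok, ccols[, 1L])],
                                  engine$peakmat[cbind(linok, ccols[, 2L])],
                                  engine$peakmat[cbind(linok, ccols[, 3L])])
    }
  }

  fwd_budget <- ifelse(status == "ok", max_steps, 0L)
  fwd <- propagate_half(seeds, init_dir, as.integer(fwd_budget), engine, U, ucnt)
  bwd_budget <- pmax(max_steps - fwd$npts, 0L)
  bwd_budget[status != "ok"] <- 0L
  bwd <- propagate_half(seeds, -init_dir, as.integer(bwd_budget), engine, U, fwd$ucnt)

  streamlines <- vector("list", n)
  lengths_mm <- numeric(n)
  for (i in seq_len(n)) {
    if (status[i] != "ok") next
    nb <- bwd$npts[i]
    nf <- fwd$npts[i]
    pts <- matrix(NA_real_, nb + 1L + nf, 3L)
    if (nb > 0L) {
      pts[seq_len(nb), ] <- cbind(bwd$ptsX[i, nb:1], bwd$ptsY[i, nb:1], bwd$ptsZ[i, nb:1])
    }
    pts[nb + 1L, ] <- seeds[i, ]
    if (nf > 0L) {
      pts[nb + 1L + seq_len(nf), ] <- cbind(fwd$ptsX[i, seq_len(nf)],
                                            fwd$ptsY[i, seq_len(nf)],
                                            fwd$ptsZ[i, seq_len(nf)])
    }
    lengths_mm[i] <- (nrow(pts) - 1L) * params$step_size
    if (lengths_mm[i] < params$min_length) {
      status[i] <- "too-short"
    } else {
      streamlines[[i]] <- pts
      status[i] <- "emitted"
    }
  }
  list(streamlines = streamlines, status = status, lengths_mm = lengths_mm,
       stop_forward = fwd$reason, stop_backward = bwd$reason)
}

#' Track a single streamline from a seed point
#'
#' Initialisation picks a uniformly random nonzero peak of the seed's voxel
#' and propagates in both senses (+p and -p) from the seed; the two
#' half-tracks share the seed point. A half-track stops when the mask falls
#' below threshold, no peak passes the angular gate, the total length would
#' exceed `max_length`, the position leaves the volume, or the update
#' degenerates. The streamline is rejected (not emitted) when its final arc
#' length is below `min_length`.
#'
#' @param seed world-mm position (length 3), inside the volume.
#' @param peaks a [peak_field()].
#' @param mask a [scalar_volume()] on the same grid.
#' @param params a [tracking_params()].
#' @param stream internal: RNG substream for this streamline.
#' @return a list with `streamline` (n x 3 matrix, or `NULL` if rejected)
#'   and `reason` (`"emitted"`, `"no-initial-peak"` or `"too-short"`).
#' @export
track_streamline <- function(seed, peaks, mask, params = tracking_params(),
                             stream = NULL) {
  vox <- voxel_at(seed, peaks$affine)
  dims <- dim(peaks$data)[1:3]
  if (any(vox < 0) || any(vox > dims - 1L)) stop("seed outside the volume")
  streams <- if (is.null(stream)) rng_streams(params$rng_seed, 1L)
             else list(NULL, stream)
  res <- track_engine(matrix(seed, 1L, 3L), peaks, mask, params, streams)
  list(streamline = res$streamlines[[1L]], reason = res$status[1L])
}

#' Track a bundle from a seed box
#'
#' Draws `seeds_per_axis^3` (or `n_seeds`) uniform seeds in the box and runs
#' [track_streamline()] logic for each, with one independent RNG substream
#' per seed. The returned tractogram's provenance records the fully resolved
#' parameter set; the rejection tally (attribute `"tally"` and field
#' `tally`) satisfies emitted + rejected = seeds.
#'
#' @param box a [seed_box()].
#' @param peaks a [peak_field()].
#' @param mask a [scalar_volume()] on the same grid.
#' @param params a [tracking_params()].
#' @param n_seeds optional explicit seed count (default `seeds_per_axis^3`).
#' @return a list of class `bundle_result`: `tractogram` ([tractogram()]),
#'   `tally` (data.frame of reason counts), `status` (per-seed reason) and
#'   `seeds` (the seed positions used).
#' @export
track_bundle <- function(box, peaks, mask, params = tracking_params(),
                         n_seeds = NULL) {
  dims <- dim(peaks$data)[1:3]
  lo <- voxel_to_world(c(0, 0, 0), peaks$affine)
  hi <- voxel_to_world(dims - 1, peaks$affine)
  bmin <- box$center - box$half_extents
  bmax <- box$center + box$half_extents
  if (any(bmax < pmin(lo, hi)) || any(bmin > pmax(lo, hi)))
    stop("seed box lies fully outside the volume")
  n <- if (is.null(n_seeds)) params$seeds_per_axis^3L else as.integer(n_seeds)
  streams <- rng_streams(params$rng_seed, n)
  seeds <- sample_seeds(box, n, stream = streams[[1L]])
  res <- track_engine(seeds, peaks, mask, params, streams)
  emitted <- res$streamlines[res$status == "emitted"]
  prov <- paste0("conetrack track mode=", params$mode,
                 " step=", params$step_size, " angle=", params$max_angle,
                 " mask_thr=", params$mask_threshold, " g=", params$puncture,
                 " len=[", params$min_length, ",", params$max_length, "]",
                 " seeds=", n, " rng=", params$rng_seed,
                 " box=", paste(c(box$center, box$half_extents), collapse = ","))
  tally <- as.data.frame(table(reason = res$status), stringsAsFactors = FALSE)
  names(tally) <- c("reason", "n")
  out <- list(tractogram = tractogram(emitted, peaks$affine, prov),
              tally = tally, status = res$status, seeds = seeds)
  attr(out, "tally") <- tally
  class(out) <- "bundle_result"
  out
}

#' @export
print.bundle_result <- function(x, ...) {
  cat(sprintf("<bundle_result: %d/%d streamlines emitted>\n",
              length(x$tractogram$streamlines), length(x$status)))
  print(x$tally, row.names = FALSE)
  invisible(x)
}
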