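#' Octree index over tractogram points
#'
#' Builds a static octree over every point of every streamline: space is
#' recursively subdivided into eight octants until a node holds at most
#' `leaf_capacity` points or `max_depth` is reached. The point positions are
#' static and known up front, so the tree is built in one pass rather than
#' by incremental insertion. Leaves store (streamline id, point index,
#' point) triples.
#'
#' @param t a non-empty [tractogram()].
#' @param leaf_capacity maximum points per leaf before splitting.
#' @param max_depth maximum subdivision depth.
#' @return an object of class `octree`.
#' @export
build_octree <- function(t, leaf_capacity = 64L, max_depth = 8L) {
  if (!length(t$streamlines)) stop("cannot index an empty tractogram")
  npts <- vapply(t$streamlines, nrow, 1L)
  pts <- do.call(rbind, t$streamlines)
  sid <- rep(seq_along(t$streamlines), npts)
  pidx <- unlist(lapply(npts, seq_len), use.names = FALSE)
  lo <- apply(pts, 2L, min) - 1e-6
  hi <- apply(pts, 2L, max) + 1e-6
  root <- octree_node(pts, sid, pidx, lo, hi, leaf_capacity, max_depth, 0L)
  structure(list(root = root, n_points = nrow(pts),
                 leaf_capacity = as.integer(leaf_capacity),
                 max_depth = as.integer(max_depth)),
            class = "octree")
}

octree_node <- function(pts, sid, pidx, lo, hi, capacity, max_depth, depth) {
  if (nrow(pts) <= capacity || depth >= max_depth) {
    return(list(lo = lo, hi = hi, leaf = TRUE,
                points = pts, sid = sid, pidx = pidx))
  }
  mid <- (lo + hi) / 2
  oct <- 1L + (pts[, 1L] >= mid[1L]) + 2L * (pts[, 2L] >= mid[2L]) +
         4L * (pts[, 3L] >= mid[3L])
  children <- vector("list", 8L)
  for (k in 1:8) {
    b <- c((k - 1L) %% 2L, ((k - 1L) %/% 2L) %% 2L, (k - 1L) %/% 4L)
    clo <- ifelse(b == 1L, mid, lo)
    chi <- ifelse(b == 1L, hi, mid)
    sel <- oct == k
    children[[k]] <- octree_node(pts[sel, , drop = FALSE], sid[sel], pidx[sel],
                                 clo, chi, capacity, max_depth, depth + 1L)
  }
  list(lo = lo, hi = hi, leaf = FALSE, children = children)
}

#' @export
print.octree <- function(x, ...) {
  cat(sprintf("<octree: %d points, leaf capacity %d, max depth %d>\n",
              x$n_points, x$leaf_capacity, x$max_depth))
  invisible(x)
}

#' Select streamlines with at least one point inside a box
#'
#' Containment is closed (boundary points count as inside). Only octree
#' nodes overlapping the box are visited; the result equals a brute-force
#' point-in-box scan.
#'
#' @param tree an [build_octree()] index.
#' @param box a [seed_box()] (axis-aligned, world mm).
#' @return sorted integer vector of streamline ids.
#' @export
select_by_box <- function(tree, box) {
  bmin <- box$center - box$half_extents
  bmax <- box$center + box$half_extents
  ids <- octree_query(tree$root, bmin, bmax)
  sort(unique(ids))
}

octree_query <- function(node, bmin, bmax) {
  if (any(node$hi < bmin) || any(node$lo > bmax)) return(integer())
  if (node$leaf) {
    if (!nrow(node$points)) return(integer())
    p <- node$points
    inside <- p[, 1L] >= bmin[1L] & p[, 1L] <= bmax[1L] &
              p[, 2L] >= bmin[2L] & p[, 2L] <= bmax[2L] &
              p[, 3L] >= bmin[3L] & p[, 3L] <= bmax[3L]
    return(node$sid[inside])
  }
  unlist(lapply(node$children, octree_query, bmin = bmin, bmax = bmax),
         use.names = FALSE)
}

#' Brute-force box selection (reference scan)
#'
#' @param t a [tractogram()].
#' @param box a [seed_box()].
#' @return sorted integer vector of streamline ids — the linear-scan
#'   counterpart of [select_by_box()].
#' @export
select_by_box_linear <- function(t, box) {
  bmin <- box$center - box$half_extents
  bmax <- box$center + box$half_extents
  hit <- vapply(t$streamlines, function(s) {
    any(s[, 1L] >= bmin[1L] & s[, 1L] <= bmax[1L] &
        s[, 2L] >= bmin[2L] & s[, 2L] <= bmax[2L] &
        s[, 3L] >= bmin[3L] & s[, 3L] <= bmax[3L])
  }, logical(1))
  which(hit)
}

#' Keep the streamline segments intersecting an axis-aligned slab
#'
#' Mirrors the 2D slice display logic: a segment `(p_i, p_{i+1})` is kept
#' iff its interval along `axis` overlaps
#' `[slice_center - thickness/2, slice_center + thickness/2]`, so segments
#' that pierce a thin slab are retained even when neither endpoint lies in
#' it.
#'
#' @param t a [tractogram()].
#' @param axis `"x"`, `"y"` or `"z"` (world axes).
#' @param slice_center slab centre along `axis`, mm.
#' @param thickness slab thickness, mm (> 0).
#' @return a data.frame with columns `streamline_id` and `segment_index`
#'   (segment i joins points i and i+1).
#' @export
slab_filter <- function(t, axis = c("x", "y", "z"), slice_center, thickness) {
  axis <- match.arg(axis)
  if (thickness <= 0) stop("thickness must be > 0")
  ax <- match(axis, c("x", "y", "z"))
  lo <- slice_center - thickness / 2
  hi <- slice_center + thickness / 2
  out_id <- list()
  out_seg <- list()
  for (i in seq_along(t$streamlines)) {
    v <- t$streamlines[[i]][, ax]
    if (length(v) < 2L) next
    a <- v[-length(v)]
    b <- v[-1L]
    keep <- pmin(a, b) <= hi & pmax(a, b) >= lo
    if (any(keep)) {
      out_id[[length(out_id) + 1L]] <- rep.int(i, sum(keep))
      out_seg[[length(out_seg) + 1L]] <- which(keep)
    }
  }
  data.frame(streamline_id = unlist(out_id, use.names = FALSE) %||% integer(),
             segment_index = unlist(out_seg, use.names = FALSE) %||% integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
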