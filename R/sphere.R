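#' Tessellated symmetric sphere meshes
#'
#' Builds a unit sphere by recursive midpoint subdivision of a regular
#' icosahedron, yielding `10 * 4^s + 2` vertices at subdivision level `s`
#' (642 at level 3, comparable in edge length to the 724-vertex symmetric
#' spheres used for fODF work). The icosahedron's vertex set is closed under
#' negation and midpoint subdivision preserves that, so the mesh is
#' antipodally symmetric by construction — every vertex has its exact
#' negation in the mesh, as required for even-order (symmetric) fODFs.
#'
#' @param subdivisions integer >= 0, number of 4-fold subdivision passes.
#' @return an object of class `sphere_mesh` with fields `vertices`
#'   (n x 3 unit rows), `faces` (m x 3, 1-based), `adjacency` (per-vertex
#'   neighbour index list), `antipode` (index of each vertex's negation) and
#'   `max_edge` (largest edge angular length, radians).
#' @examples
#' m <- make_icosphere(3)
#' nrow(m$vertices) # 642
#' @export
make_icosphere <- function(subdivisions) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    res <- subdivide_once(v, f)
    v <- res$vertices
    f <- res$faces
  }
  v <- v / sqrt(rowSums(v^2))
  adjacency <- adjacency_from_faces(f, nrow(v))
  antipode <- match_antipodes(v)
  edges <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]))
  dots <- rowSums(v[edges[, 1], , drop = FALSE] * v[edges[, 2], , drop = FALSE])
  structure(list(vertices = v, faces = f, adjacency = adjacency,
                 antipode = antipode,
                 max_edge = max(acos(pmin(pmax(dots, -1), 1))),
                 cache = new.env(parent = emptyenv())),
            class = "sphere_mesh")
}

subdivide_once <- function(v, f) {
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  midpoint_cache <- new.env(parent = emptyenv())
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    k <- key(i, j)
    idx <- midpoint_cache[[k]]
    if (is.null(idx)) {
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts[[length(verts) + 1L]] <<- p
      idx <- length(verts)
      midpoint_cache[[k]] <- idx
    }
    idx
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts), faces = newf)
}

adjacency_from_faces <- function(f, n) {
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- rbind(edges, edges[, c(2, 1)])
  edges <- unique(edges)
  split(edges[, 2], factor(edges[, 1], levels = seq_len(n)))
}

match_antipodes <- function(v) {
  ant <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    d <- rowSums(sweep(v, 2L, -v[i, ])^2)
    j <- which.min(d)
    if (d[j] > 1e-12) stop("mesh is not antipodally symmetric")
    ant[i] <- j
  }
  ant
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat(sprintf("<sphere_mesh: %d vertices, %d faces, max edge %.2f deg>\n",
              nrow(x$vertices), nrow(x$faces), x$max_edge * 180 / pi))
  invisible(x)
}

# per-mesh cache of, for each vertex, the other vertices sorted by angular
# distance (used by the uncertainty-angle traversal); built lazily
mesh_angle_order <- function(mesh, vertex) {
  key <- as.character(vertex)
  hit <- mesh$cache[[key]]
  if (!is.null(hit)) return(hit)
  dots <- drop(mesh$vertices %*% mesh$vertices[vertex, ])
  ang <- acos(pmin(pmax(dots, -1), 1))
  ord <- order(ang)
  res <- list(order = ord, angle = ang[ord])
  mesh$cache[[key]] <- res
  res
}
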