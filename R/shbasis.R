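#' Real symmetric spherical-harmonic basis on a sphere mesh
#'
#' Assembles the matrix of the real, orthonormal spherical-harmonic basis
#' restricted to even degrees (the symmetric basis used for fODFs) at the
#' mesh vertices. Coefficients are ordered by degree l = 0, 2, ..., lmax and,
#' within a degree, by order m = -l, ..., l; negative orders carry the
#' sin(|m| phi) terms and positive orders the cos(m phi) terms. For
#' `lmax = 8` this gives (8+1)(8+2)/2 = 45 columns. Rows for antipodal
#' vertices are identical (even degrees only).
#'
#' @param mesh a [make_icosphere()] mesh (any object with unit `vertices`).
#' @param lmax even, non-negative SH order.
#' @return an `n_vertices x n_coeffs` matrix.
#' @export
sh_basis_matrix <- function(mesh, lmax) {
  if (lmax < 0 || lmax %% 2 != 0) stop("lmax must be even and >= 0")
  v <- mesh$vertices
  theta <- acos(pmin(pmax(v[, 3], -1), 1))
  phi <- atan2(v[, 2], v[, 1])
  ct <- cos(theta)
  B <- matrix(0, nrow(v), n_sh_coeffs(lmax))
  col <- 0L
  for (l in seq(0L, lmax, by = 2L)) {
    # associated Legendre P_l^m(cos theta), rows m = 0..l (Condon-Shortley)
    P <- if (l == 0L) matrix(1, 1L, length(ct)) else pracma::legendre(l, ct)
    for (m in seq(-l, l)) {
      col <- col + 1L
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      B[, col] <- if (m < 0L) {
        sqrt(2) * nrm * P[am + 1L, ] * sin(am * phi)
      } else if (m == 0L) {
        nrm * P[1L, ]
      } else {
        sqrt(2) * nrm * P[am + 1L, ] * cos(am * phi)
      }
    }
  }
  B
}

#' Evaluate an fODF's SH coefficients on a sphere mesh
#'
#' @param coeffs SH coefficient vector (length `(lmax+1)(lmax+2)/2`).
#' @param mesh a [make_icosphere()] mesh.
#' @param basis optionally a precomputed [sh_basis_matrix()] (must match
#'   `mesh` and the coefficient length).
#' @return an object of class `spherical_function`: list of `values`
#'   (one real per vertex) and `mesh`.
#' @export
evaluate_fodf <- function(coeffs, mesh, basis = NULL) {
  lmax <- lmax_for_coeffs(length(coeffs))
  if (is.null(basis)) basis <- cached_basis(mesh, lmax)
  if (ncol(basis) != length(coeffs)) stop("coefficient length does not match basis")
  spherical_function(drop(basis %*% coeffs), mesh)
}

#' @rdname evaluate_fodf
#' @param values one real per mesh vertex.
#' @export
spherical_function <- function(values, mesh) {
  stopifnot(length(values) == nrow(mesh$vertices), all(is.finite(values)))
  structure(list(values = as.numeric(values), mesh = mesh),
            class = "spherical_function")
}

lmax_for_coeffs <- function(nc) {
  lmax <- (sqrt(8 * nc + 1) - 3) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop(sprintf("coefficient length %d does not match any even SH order", nc))
  as.integer(round(lmax))
}

cached_basis <- function(mesh, lmax) {
  key <- paste0("basis_", lmax)
  B <- mesh$cache[[key]]
  if (is.null(B)) {
    B <- sh_basis_matrix(mesh, lmax)
    mesh$cache[[key]] <- B
  }
  B
}

#' Fit SH coefficients to a sampled spherical function
#'
#' Least-squares projection onto the even-degree real SH basis. For a
#' function already band-limited at `lmax` the fit is exact, so
#' `evaluate_fodf(sf_to_sh(f, lmax), mesh)` reproduces `f`.
#'
#' @param f a [spherical_function()].
#' @param lmax even SH order of the fit; the mesh must have at least
#'   `(lmax+1)(lmax+2)/2` vertices.
#' @return the coefficient vector.
#' @export
sf_to_sh <- function(f, lmax) {
  B <- cached_basis(f$mesh, lmax)
  if (nrow(B) < ncol(B)) stop("mesh too coarse: underdetermined SH fit")
  qr.coef(cached_basis_qr(f$mesh, lmax), f$values)
}

cached_basis_qr <- function(mesh, lmax) {
  key <- paste0("basisqr_", lmax)
  q <- mesh$cache[[key]]
  if (is.null(q)) {
    q <- qr(cached_basis(mesh, lmax))
    mesh$cache[[key]] <- q
  }
  q
}
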