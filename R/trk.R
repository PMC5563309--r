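#' Streamline bundles (tractograms)
#'
#' A streamline is an ordered sequence of 3D points in world mm, stored as an
#' n x 3 matrix; tracker-generated streamlines have consecutive points
#' exactly one step size apart. A tractogram bundles streamlines with the
#' [affine()] of their reference grid and a free-text provenance record (the
#' resolved parameter set of the run that produced them), which round-trips
#' through TrackVis save/load.
#'
#' @param streamlines list of n x 3 numeric matrices (n >= 2 each).
#' @param affine reference-grid [affine()].
#' @param provenance free-text parameter record.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine, provenance = "") {
  stopifnot(is.list(streamlines))
  for (s in streamlines) {
    stopifnot(is.matrix(s), ncol(s) == 3L, nrow(s) >= 2L, all(is.finite(s)))
  }
  structure(list(streamlines = streamlines, affine = affine,
                 provenance = as.character(provenance)[1L]),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  npts <- if (length(x$streamlines)) vapply(x$streamlines, nrow, 1L) else integer()
  cat(sprintf("<tractogram: %d streamlines, %d points%s>\n",
              length(x$streamlines), sum(npts),
              if (nzchar(x$provenance)) ", with provenance" else ""))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Arc lengths of the streamlines in a tractogram
#' @param t a [tractogram()].
#' @return numeric vector of arc lengths in mm.
#' @export
streamline_lengths <- function(t) {
  vapply(t$streamlines, function(s) {
    if (nrow(s) < 2L) return(0)
    sum(sqrt(rowSums(diff(s)^2)))
  }, numeric(1))
}

# ---- TrackVis format -------------------------------------------------------
# 1000-byte header, little endian. Points on disk are in "voxmm" with the
# voxel *corner* at the origin: voxmm = (voxel + 0.5) * voxel_size, where
# voxel is our centre-at-integer 0-based coordinate. The provenance string is
# carried in the header's 444-byte reserved field.

TRK_HDR_SIZE <- 1000L

trk_pad_raw <- function(txt, n) {
  r <- charToRaw(enc2utf8(txt))
  if (length(r) >= n) r <- r[seq_len(n - 1L)]  # keep a trailing NUL
  c(r, raw(n - length(r)))
}

#' Read and write TrackVis streamline files
#'
#' Points are converted between the on-disk voxel-mm convention and world mm
#' using the header affine, so coordinates round-trip to within 1e-4 mm (the
#' file stores 32-bit floats); the streamline count round-trips exactly.
#'
#' @param t a [tractogram()].
#' @param path file path (`.trk`).
#' @param dim integer grid dimensions recorded in the header.
#' @return `read_tractogram` returns a [tractogram()]; `write_tractogram`
#'   returns `path` invisibly.
#' @export
write_tractogram <- function(t, path, dim = c(0L, 0L, 0L)) {
  stopifnot(inherits(t, "tractogram"))
  vs <- affine_voxel_size(t$affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(trk_pad_raw("TRACK", 6L), con)
  writeBin(as.integer(dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")     # origin (unused)
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(raw(200L), con)                                     # scalar names
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(raw(200L), con)                                     # property names
  writeBin(as.numeric(t(unclass(t$affine))), con, size = 4L, endian = "little")
  writeBin(trk_pad_raw(t$provenance, 444L), con)               # reserved
  writeBin(trk_pad_raw("RAS", 4L), con)                        # voxel_order
  writeBin(raw(4L), con)                                       # pad2
  writeBin(numeric(6L), con, size = 4L, endian = "little")     # orientation
  writeBin(raw(2L), con)                                       # pad1
  writeBin(raw(6L), con)                                       # invert/swap flags
  writeBin(length(t$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(TRK_HDR_SIZE, con, size = 4L, endian = "little")
  for (s in t$streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    vox <- world_to_voxel(s, t$affine)
    voxmm <- sweep(vox + 0.5, 2L, vs, `*`)
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_tractogram
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop("malformed TrackVis header (bad magic)")
  readBin(con, "integer", 3L, size = 2L, endian = "little")          # dim
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")          # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  m <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
              4L, 4L, byrow = TRUE)
  reserved <- readBin(con, "raw", 444L)
  readBin(con, "raw", 4L + 4L)                                       # order, pad2
  readBin(con, "numeric", 6L, size = 4L, endian = "little")
  readBin(con, "raw", 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 4L, endian = "little")          # version
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, TRK_HDR_SIZE))
    stop("malformed TrackVis header (hdr_size != 1000)")
  if (all(m == 0)) m <- diag(c(vs, 1))  # legacy files without vox_to_ras
  aff <- affine(m)
  if (any(vs <= 0)) vs <- affine_voxel_size(aff)
  nul <- which(reserved == as.raw(0L))[1L]
  provenance <- rawToChar(if (is.na(nul)) reserved else reserved[seq_len(nul - 1L)])
  streamlines <- list()
  i <- 0L
  repeat {
    if (n_count > 0L && i >= n_count) break
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    pts <- readBin(con, "numeric", np * (3L + n_scalars), size = 4L,
                   endian = "little")
    pts <- matrix(pts, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L, endian = "little")
    vox <- sweep(pts, 2L, vs, `/`) - 0.5
    i <- i + 1L
    streamlines[[i]] <- voxel_to_world(vox, aff)
  }
  t <- structure(list(streamlines = streamlines, affine = aff,
                      provenance = provenance), class = "tractogram")
  t
}
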