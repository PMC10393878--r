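#' Write a vessel surface to an STL file
#'
#' The lumen surface is the interchange format between the reconstruction
#' and simulation stages, so both the compact binary dialect (80-byte
#' header, 32-bit little-endian floats) and the ASCII dialect are supported.
#' Coordinates are written in millimetres; STL stores 32-bit floats, so a
#' write/read round trip preserves vertices only to single precision.
#'
#' @param geometry A `vessel_geometry` with a watertight surface.
#' @param path Output file path.
#' @param ascii Write the ASCII dialect instead of binary (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_stl <- function(geometry, path, ascii = FALSE) {
  if (!is_watertight(geometry))
    .stopf("write_stl: surface is not watertight")
  v <- geometry$vertices
  f <- geometry$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  nrm <- .cross3(p2 - p1, p3 - p1)
  len <- .row_norms(nrm)
  len[len == 0] <- 1
  nrm <- nrm / len
  nf <- nrow(f)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid vessel", con)
    block <- sprintf(
      paste0("facet normal %.9e %.9e %.9e\n outer loop\n",
             "  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n",
             "  vertex %.9e %.9e %.9e\n endloop\nendfacet"),
      nrm[, 1], nrm[, 2], nrm[, 3],
      p1[, 1], p1[, 2], p1[, 3],
      p2[, 1], p2[, 2], p2[, 3],
      p3[, 1], p3[, 2], p3[, 3])
    writeLines(block, con)
    writeLines("endsolid vessel", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("vessel lumen surface (binary STL)",
                                width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 per facet (12 floats), then attr count
    dat <- t(cbind(nrm, p1, p2, p3))
    for (i in seq_len(nf)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an STL surface as a vessel geometry
#'
#' Accepts binary or ASCII STL. The triangle soup is welded into a shared
#' vertex list, an approximate centerline is reconstructed by slicing the
#' vertices along the principal axis and averaging, and the radius profile
#' can then be re-extracted with [extract_radius_profile()].
#'
#' @param path STL file path.
#' @param centerline_bins Number of slices used for the centerline estimate.
#' @return A `vessel_geometry` (with reconstructed, approximate centerline).
#' @export
read_stl <- function(path, centerline_bins = 64) {
  raw5 <- readBin(path, "raw", n = 5L)
  if (length(raw5) < 5L)
    .stopf("read_stl: malformed STL '%s': file shorter than 5 bytes", path)
  tri <- if (identical(rawToChar(raw5), "solid") && .stl_is_ascii(path)) {
    .read_stl_ascii(path)
  } else {
    .read_stl_binary(path)
  }
  if (nrow(tri) == 0L)
    .stopf("read_stl: '%s' contains an empty facet list", path)
  .geometry_from_triangles(tri, centerline_bins)
}

# a file starting with "solid" can still be binary; require a "facet" token
# in the first chunk of printable text
.stl_is_ascii <- function(path) {
  chunk <- readBin(path, "raw", n = 1024L)
  txt <- suppressWarnings(rawToChar(chunk[chunk != as.raw(0)]))
  grepl("facet", txt, fixed = TRUE) || grepl("endsolid", txt, fixed = TRUE)
}

.read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 84)
    .stopf("read_stl: malformed binary STL: header truncated at byte %d", sz)
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (nf < 0 || sz < 84 + 50 * as.numeric(nf))
    .stopf(paste0("read_stl: malformed binary STL: facet count %d ",
                  "inconsistent with file size %d (expected %d bytes, ",
                  "truncation at byte offset %d)"),
           nf, sz, 84 + 50 * nf, sz)
  if (nf == 0L) return(matrix(numeric(0), ncol = 9))
  body <- readBin(con, "raw", n = 50L * nf)
  dim(body) <- c(50L, nf)
  floats <- readBin(as.vector(body[1:48, ]), "numeric",
                    n = 12L * nf, size = 4L, endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  m[, 4:12, drop = FALSE]  # drop stored normals, keep 3 vertices
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0)
    .stopf("read_stl: malformed ASCII STL: %d vertex lines (not a multiple of 3)",
           length(vl))
  if (length(vl) == 0L) return(matrix(numeric(0), ncol = 9))
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x) {
    v <- suppressWarnings(as.numeric(x[2:4]))
    if (anyNA(v)) .stopf("read_stl: malformed ASCII STL vertex line: '%s'",
                         paste(x, collapse = " "))
    v
  }, numeric(3)))
  matrix(t(nums), ncol = 9L, byrow = TRUE)
}

# weld a (nf x 9) triangle soup into shared vertices + faces, reconstruct
# an approximate centerline along the principal axis
.geometry_from_triangles <- function(tri, centerline_bins) {
  nf <- nrow(tri)
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uid <- match(key, key[!duplicated(key)])
  verts <- pts[!duplicated(key), , drop = FALSE]
  faces <- cbind(uid[seq_len(nf)], uid[nf + seq_len(nf)],
                 uid[2L * nf + seq_len(nf)])

  ctr <- colMeans(verts)
  sv <- svd(sweep(verts, 2, ctr), nu = 0, nv = 1)
  axis <- sv$v[, 1]
  proj <- as.vector(sweep(verts, 2, ctr) %*% axis)
  # cluster projections that differ by less than a small fraction of the
  # axial range (float32 storage noise in binary STL) onto their cluster
  # mean, then snap the interior bin boundaries to midpoints between
  # adjacent clusters so no vertex ever sits on a boundary (vertex rings
  # would otherwise flip bins between the two STL dialects)
  ord <- order(proj)
  tolc <- diff(range(proj)) * 1e-5
  cl_id <- cumsum(c(1, diff(proj[ord]) > tolc))
  cl_mean <- as.vector(tapply(proj[ord], cl_id, mean))
  proj[ord] <- cl_mean[cl_id]
  uv <- sort(unique(proj))
  br <- seq(min(proj), max(proj), length.out = centerline_bins + 1L)
  if (length(uv) > 1L) {
    mids <- (uv[-1] + uv[-length(uv)]) / 2
    inner <- vapply(br[-c(1L, length(br))], function(b)
      mids[which.min(abs(mids - b))], numeric(1))
    br <- c(br[1L], inner, br[length(br)])
    br <- br[!duplicated(br)]
  }
  n_bins <- length(br) - 1L
  bin <- pmin(pmax(findInterval(proj, br), 1L), n_bins)
  keep <- sort(unique(bin))
  cl <- t(vapply(keep, function(b)
    colMeans(verts[bin == b, , drop = FALSE]), numeric(3)))
  seg <- diff(cl)
  arc <- c(0, cumsum(sqrt(rowSums(seg^2))))
  # rough per-slice radius: mean in-slice distance to the slice centroid
  rad <- vapply(seq_along(keep), function(k) {
    pts_k <- verts[bin == keep[k], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts_k, 2, cl[k, ])^2)))
  }, numeric(1))
  geom <- structure(list(
    centerline = cl, arclength = arc, tangent = NULL,
    radius_profile = rad,
    vertices = verts, faces = faces,
    arclength_total = arc[length(arc)], spec = NULL
  ), class = "vessel_geometry")
  geom$tangent <- .finite_diff_tangent(geom)
  # orient outward: flip winding if the signed volume is negative
  if (.surface_volume(geom) < 0) geom$faces <- geom$faces[, c(1L, 3L, 2L)]
  geom
}
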