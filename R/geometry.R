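#' Describe a single focal stenosis in a tubular vessel
#'
#' A `stenosis_spec` parametrises an idealised coronary lumen: a tube of
#' `reference_diameter` narrowed by `stenosis_pct` percent diameter reduction
#' at the lesion throat, with a smooth cosine taper over `lesion_length`.
#' Percent diameter stenosis is the clinical descriptor (30--90% covers the
#' usual interventional case mix); the throat diameter is
#' `reference_diameter * (1 - stenosis_pct / 100)`.
#'
#' @param reference_diameter Healthy lumen diameter (mm).
#' @param stenosis_pct Percent diameter reduction at the throat, in `[0, 100)`.
#' @param lesion_length Axial extent of the narrowing (mm), > 0.
#' @param lesion_center Arclength position of the throat (mm). The lesion
#'   `[lesion_center - lesion_length/2, lesion_center + lesion_length/2]`
#'   must fit inside `[0, vessel_length]`.
#' @param eccentricity Fraction in `[0, 1]` displacing the lumen centre
#'   laterally within the lesion (0 = axisymmetric). The cross-section stays
#'   circular, so cross-sectional area is preserved.
#' @param vessel_length Total vessel length (mm).
#' @param curvature_radius Optional centerline radius of curvature (mm);
#'   `NULL` for a straight vessel.
#' @return An object of class `stenosis_spec`.
#' @examples
#' spec <- stenosis_spec(reference_diameter = 3, stenosis_pct = 60,
#'                       lesion_length = 10, lesion_center = 15,
#'                       vessel_length = 30)
#' spec$throat_diameter  # 1.2 mm
#' @export
stenosis_spec <- function(reference_diameter, stenosis_pct, lesion_length,
                          lesion_center, eccentricity = 0,
                          vessel_length, curvature_radius = NULL) {
  if (!is.numeric(reference_diameter) || reference_diameter <= 0)
    .stopf("invalid stenosis_spec: reference_diameter must be > 0 (got %s)",
           format(reference_diameter))
  if (stenosis_pct < 0 || stenosis_pct >= 100)
    .stopf("invalid stenosis_spec: stenosis_pct must satisfy 0 <= pct < 100 (got %s)",
           format(stenosis_pct))
  if (lesion_length <= 0)
    .stopf("invalid stenosis_spec: lesion_length must be > 0 (got %s)",
           format(lesion_length))
  if (vessel_length <= 0)
    .stopf("invalid stenosis_spec: vessel_length must be > 0 (got %s)",
           format(vessel_length))
  if (lesion_center - lesion_length / 2 < 0 ||
      lesion_center + lesion_length / 2 > vessel_length)
    .stopf(paste0("invalid stenosis_spec: lesion [%s, %s] mm does not fit ",
                  "inside [0, %s] mm"),
           format(lesion_center - lesion_length / 2),
           format(lesion_center + lesion_length / 2), format(vessel_length))
  if (eccentricity < 0 || eccentricity > 1)
    .stopf("invalid stenosis_spec: eccentricity must lie in [0, 1] (got %s)",
           format(eccentricity))
  if (!is.null(curvature_radius) && curvature_radius <= 0)
    .stopf("invalid stenosis_spec: curvature_radius must be > 0 or NULL")
  structure(list(
    reference_diameter = reference_diameter,
    stenosis_pct = stenosis_pct,
    lesion_length = lesion_length,
    lesion_center = lesion_center,
    eccentricity = eccentricity,
    vessel_length = vessel_length,
    curvature_radius = curvature_radius,
    throat_diameter = reference_diameter * (1 - stenosis_pct / 100)
  ), class = "stenosis_spec")
}

#' @export
print.stenosis_spec <- function(x, ...) {
  cat(sprintf(
    "<stenosis_spec> D_ref %.2f mm, %.0f%% stenosis (throat %.2f mm),\n",
    x$reference_diameter, x$stenosis_pct, x$throat_diameter))
  cat(sprintf("  lesion %.1f mm centred at %.1f mm, vessel %.1f mm, ecc %.2f%s\n",
              x$lesion_length, x$lesion_center, x$vessel_length,
              x$eccentricity,
              if (is.null(x$curvature_radius)) ", straight"
              else sprintf(", curvature radius %.0f mm", x$curvature_radius)))
  invisible(x)
}

# Lumen radius (mm) at arclength s (mm): cosine taper inside the lesion.
.spec_radius <- function(spec, s) {
  w <- numeric(length(s))
  inside <- abs(s - spec$lesion_center) <= spec$lesion_length / 2
  w[inside] <- 0.5 * (1 + cos(2 * pi * (s[inside] - spec$lesion_center) /
                                spec$lesion_length))
  spec$reference_diameter / 2 * (1 - spec$stenosis_pct / 100 * w)
}

# Lateral offset (mm) of the lumen centre: a fraction of the local radius
# deficit, so the offset fades with the taper and the section stays circular.
.spec_offset <- function(spec, s) {
  r_ref <- spec$reference_diameter / 2
  spec$eccentricity * (r_ref - .spec_radius(spec, s))
}

# Centerline points (mm) and parallel-transported frame for arclengths s.
.spec_frame <- function(spec, s) {
  n <- length(s)
  if (is.null(spec$curvature_radius)) {
    base <- cbind(0, 0, s)
    tang <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
    e1 <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
    e2 <- matrix(rep(c(0, 1, 0), each = n), ncol = 3)
  } else {
    Rc <- spec$curvature_radius
    phi <- s / Rc
    base <- cbind(Rc * (1 - cos(phi)), 0, Rc * sin(phi))
    tang <- cbind(sin(phi), 0, cos(phi))
    e1 <- cbind(cos(phi), 0, -sin(phi))   # in-plane normal, transported
    e2 <- matrix(rep(c(0, 1, 0), each = n), ncol = 3)
  }
  off <- .spec_offset(spec, s)
  list(center = base + off * e1, tangent = tang, e1 = e1, e2 = e2)
}

#' Generate a triangulated stenosed-vessel lumen
#'
#' Builds the ground-truth geometry all downstream stages consume: an ordered
#' centerline, the analytic radius profile sampled along it, and a closed,
#' consistently outward-oriented triangulated lumen surface (side rings plus
#' end-cap fans).
#'
#' @param spec A [stenosis_spec()].
#' @param axial_samples Number of axial intervals (>= 16).
#' @param circumferential_samples Number of vertices per ring (>= 8).
#' @return An object of class `vessel_geometry` with fields `centerline`
#'   (points, mm), `arclength`, `radius_profile` (mm), `vertices`, `faces`
#'   (triangles, outward normals), `arclength_total`, and the generating
#'   `spec`.
#' @examples
#' geom <- make_stenosed_vessel(
#'   stenosis_spec(3, 60, 10, 15, vessel_length = 30),
#'   axial_samples = 64, circumferential_samples = 32)
#' min(geom$radius_profile)  # ~0.6 mm throat radius
#' @export
make_stenosed_vessel <- function(spec, axial_samples = 128,
                                 circumferential_samples = 48) {
  stopifnot(inherits(spec, "stenosis_spec"))
  if (axial_samples < 16)
    .stopf("axial_samples must be >= 16 (got %d)", axial_samples)
  if (circumferential_samples < 8)
    .stopf("circumferential_samples must be >= 8 (got %d)",
           circumferential_samples)
  na <- as.integer(axial_samples)
  nc <- as.integer(circumferential_samples)
  s <- seq(0, spec$vessel_length, length.out = na + 1L)
  fr <- .spec_frame(spec, s)
  r <- .spec_radius(spec, s)

  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  # ring vertices: (na+1) rings of nc points, then the two cap centres
  verts <- matrix(0, nrow = (na + 1L) * nc + 2L, ncol = 3)
  for (i in seq_len(na + 1L)) {
    ring <- fr$center[rep(i, nc), , drop = FALSE] +
      r[i] * (cos(theta) %o% fr$e1[i, ] + sin(theta) %o% fr$e2[i, ])
    verts[((i - 1L) * nc + 1L):(i * nc), ] <- ring
  }
  c_in <- (na + 1L) * nc + 1L
  c_out <- (na + 1L) * nc + 2L
  verts[c_in, ] <- fr$center[1L, ]
  verts[c_out, ] <- fr$center[na + 1L, ]

  idx <- function(i, j) (i - 1L) * nc + ((j - 1L) %% nc) + 1L
  ii <- rep(seq_len(na), each = nc)
  jj <- rep(seq_len(nc), times = na)
  a <- idx(ii, jj); b <- idx(ii, jj + 1L)
  cc <- idx(ii + 1L, jj + 1L); d <- idx(ii + 1L, jj)
  side <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  j <- seq_len(nc)
  cap_in <- cbind(c_in, idx(1L, j + 1L), idx(1L, j))
  cap_out <- cbind(c_out, idx(na + 1L, j), idx(na + 1L, j + 1L))
  faces <- rbind(side, cap_in, cap_out)
  colnames(faces) <- NULL

  structure(list(
    centerline = fr$center, arclength = s, radius_profile = r,
    tangent = fr$tangent, e1 = fr$e1, e2 = fr$e2,
    vertices = verts, faces = faces,
    arclength_total = spec$vessel_length, spec = spec
  ), class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> length %.1f mm, radius %.2f-%.2f mm, %d vertices / %d triangles\n",
    x$arclength_total, min(x$radius_profile), max(x$radius_profile),
    nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that a triangulated surface is closed and consistently oriented
#'
#' A surface is watertight when every directed edge appears exactly once,
#' which implies every undirected edge is shared by exactly two triangles
#' with opposite winding.
#'
#' @param geometry A `vessel_geometry` (or any list with `vertices`/`faces`).
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(geometry) {
  f <- geometry$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  directed <- paste(from, to)
  if (anyDuplicated(directed) > 0L) return(FALSE)
  undirected <- paste(pmin(from, to), pmax(from, to))
  all(table(undirected) == 2L)
}

# Signed volume of the closed surface (mm^3); positive for outward normals.
.surface_volume <- function(geometry) {
  v <- geometry$vertices
  f <- geometry$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(p1 * .cross3(p2, p3))) / 6
}

#' Extract the lumen radius profile from a triangulated surface
#'
#' At each of `n_stations` arclength stations a plane perpendicular to the
#' centerline cuts the surface; the effective radius is `sqrt(area / pi)` of
#' the cut cross-section. The cross-section area is accumulated from the
#' oriented triangle/plane intersection segments, so no polygon assembly is
#' required, but the surface must be watertight and consistently oriented.
#'
#' @param geometry A `vessel_geometry`.
#' @param n_stations Number of stations, spread over the interior of the
#'   vessel (end caps are avoided).
#' @return A data.frame with columns `arclength` (mm), `area` (mm^2) and
#'   `radius` (mm).
#' @export
extract_radius_profile <- function(geometry, n_stations = 128) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (!is_watertight(geometry))
    .stopf("extract_radius_profile: surface is not watertight")
  L <- geometry$arclength_total
  eps <- L * 0.004
  st <- seq(eps, L - eps, length.out = n_stations)
  ctr <- apply(geometry$centerline, 2, function(col)
    approx(geometry$arclength, col, xout = st)$y)
  tng <- apply(geometry$tangent %||% .finite_diff_tangent(geometry), 2,
               function(col) approx(geometry$arclength, col, xout = st)$y)
  tng <- tng / .row_norms(tng)

  v <- geometry$vertices
  f <- geometry$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  r_max <- max(geometry$radius_profile)

  area <- vapply(seq_len(n_stations), function(k) {
    .plane_cut_area(p1, p2, p3, ctr[k, ], tng[k, ], r_max)
  }, numeric(1))
  data.frame(arclength = st, area = area, radius = sqrt(pmax(area, 0) / pi))
}

.finite_diff_tangent <- function(geometry) {
  cl <- geometry$centerline
  n <- nrow(cl)
  t <- rbind(cl[2, ] - cl[1, ],
             cl[3:n, , drop = FALSE] - cl[1:(n - 2), , drop = FALSE],
             cl[n, ] - cl[n - 1, ])
  t / .row_norms(t)
}

# Signed cross-section area of the plane cut (point p0, unit normal nrm).
# Each triangle crossing the plane contributes an oriented segment; the sum
# of 0.5 * nrm . ((a - p0) x (b - p0)) over consistently oriented segments
# equals the enclosed area for an outward-oriented closed surface.
.plane_cut_area <- function(p1, p2, p3, p0, nrm, r_max) {
  d1 <- (p1[, 1] - p0[1]) * nrm[1] + (p1[, 2] - p0[2]) * nrm[2] + (p1[, 3] - p0[3]) * nrm[3]
  d2 <- (p2[, 1] - p0[1]) * nrm[1] + (p2[, 2] - p0[2]) * nrm[2] + (p2[, 3] - p0[3]) * nrm[3]
  d3 <- (p3[, 1] - p0[1]) * nrm[1] + (p3[, 2] - p0[2]) * nrm[2] + (p3[, 3] - p0[3]) * nrm[3]
  cross <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (!any(cross)) return(0)
  idx <- which(cross)
  acc <- 0
  pts_far <- 0L
  for (i in idx) {
    dv <- c(d1[i], d2[i], d3[i])
    tri <- rbind(p1[i, ], p2[i, ], p3[i, ])
    # find the two edges with a sign change (vertices exactly on the plane
    # are nudged to the positive side for robustness)
    dv[dv == 0] <- 1e-300
    segs <- list()
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      if (dv[e[1]] * dv[e[2]] < 0) {
        tt <- dv[e[1]] / (dv[e[1]] - dv[e[2]])
        segs[[length(segs) + 1L]] <- tri[e[1], ] + tt * (tri[e[2], ] - tri[e[1], ])
      }
    }
    if (length(segs) != 2L) next
    a <- segs[[1L]]; b <- segs[[2L]]
    # orient (a, b) so the segment direction matches nrm x triangle normal,
    # which makes the winding consistent with the surface orientation
    tn <- .cross3(matrix(tri[2, ] - tri[1, ], 1), matrix(tri[3, ] - tri[1, ], 1))[1, ]
    sdir <- .cross3(matrix(nrm, 1), matrix(tn, 1))[1, ]
    if (sum((b - a) * sdir) < 0) { tmp <- a; a <- b; b <- tmp }
    if (sqrt(sum((a - p0)^2)) > 3 * r_max || sqrt(sum((b - p0)^2)) > 3 * r_max)
      pts_far <- pts_far + 1L
    ra <- a - p0; rb <- b - p0
    acc <- acc + 0.5 * sum(nrm * .cross3(matrix(ra, 1), matrix(rb, 1))[1, ])
  }
  if (pts_far > 0L)
    .stopf(paste0("extract_radius_profile: station plane intersects the ",
                  "surface more than once (severe tortuosity; %d far ",
                  "intersection points)"), pts_far)
  acc
}

#' Estimate percent diameter stenosis from a radius profile
#'
#' The reference radius is taken as the mean of the profile outside the
#' narrowed region (proximal and distal 15% of stations); the throat is the
#' profile minimum.
#'
#' @param profile A data.frame from [extract_radius_profile()].
#' @return Estimated percent diameter stenosis.
#' @export
estimate_stenosis_pct <- function(profile) {
  n <- nrow(profile)
  k <- max(2L, floor(0.15 * n))
  r_ref <- mean(c(profile$radius[seq_len(k)],
                  profile$radius[(n - k + 1L):n]))
  100 * (1 - min(profile$radius) / r_ref)
}
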