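# Parametric stem geometry: two-half superellipse cross sections, skeleton
# with Bezier neck transition, cubic-spline loft, cement mantle sections.
#
# Coordinate convention (fixed throughout the package): prosthesis axis = +z
# (distal tip at z = 0), frontal/anterior = +x, medial = +y. Lengths in mm,
# angles in degrees in configuration, radians internally. Each cross section
# lies in a plane whose local x axis is the global +x (the a1/a2 semiaxes)
# and whose local y axis carries the common semiaxis b (medial-lateral).

#' Cross-section parameters of a two-half superellipse
#'
#' A stem cross section is assembled from two superellipse halves
#' \eqn{|x/a|^p + |y/b|^p = 1} sharing the common semiaxis `b` (the
#' medial-lateral axis) and the exponent `p`: the half on the anterior side
#' (`x >= 0`) uses semiaxis `a1`, the posterior half uses `a2`. `p = 2` gives
#' an ellipse; larger exponents approach a rectangular ("trapezoidal")
#' profile.
#'
#' @param a1 anterior semiaxis, mm (> 0)
#' @param a2 posterior semiaxis, mm (> 0)
#' @param b common medial-lateral semiaxis, mm (> 0)
#' @param p integer shape exponent, >= 2
#' @return object of class `cross_section`
#' @examples
#' cs <- cross_section(6, 6, 6, 2)   # circle of radius 6
#' section_properties(cs)$area       # ~ pi * 36
#' @export
cross_section <- function(a1, a2, b, p) {
  if (!is_number(a1) || !is_number(a2) || !is_number(b) ||
      a1 <= 0 || a2 <= 0 || b <= 0)
    stop_stemopt("cross-section semiaxes must be positive numbers",
                 "invalid_parameter")
  if (!is_number(p) || p < 2 || abs(p - round(p)) > 1e-9)
    stop_stemopt("cross-section exponent p must be an integer >= 2",
                 "invalid_parameter")
  structure(list(a1 = a1, a2 = a2, b = b, p = as.integer(round(p))),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section: a1=%.3g a2=%.3g b=%.3g mm, p=%d\n",
              x$a1, x$a2, x$b, x$p))
  invisible(x)
}

#' Boundary point of a cross-section profile
#'
#' Evaluates the closed boundary curve of a two-half superellipse at the
#' parametric angle(s) `angle`. The curve is continuous at the junction with
#' the b axis and closed over one period.
#'
#' @param cs a [cross_section()]
#' @param angle parametric angle(s), radians
#' @return matrix with columns `x`, `y` (mm), one row per angle
#' @export
profile_point <- function(cs, angle) {
  if (!inherits(cs, "cross_section"))
    stop_stemopt("cs must be a cross_section", "invalid_parameter")
  ca <- cos(angle)
  sa <- sin(angle)
  a <- ifelse(ca >= 0, cs$a1, cs$a2)
  e <- 2 / cs$p
  cbind(x = a * sign(ca) * abs(ca)^e,
        y = cs$b * sign(sa) * abs(sa)^e)
}

# Polar radius of the profile in direction phi (radians from +x).
# Closed form from |r cos(phi)/a|^p + |r sin(phi)/b|^p = 1.
superellipse_radius <- function(cs, phi) {
  a <- ifelse(cos(phi) >= 0, cs$a1, cs$a2)
  (abs(cos(phi) / a)^cs$p + abs(sin(phi) / cs$b)^cs$p)^(-1 / cs$p)
}

#' Closed-form area of a full superellipse
#'
#' Area of \eqn{|x/a|^p + |y/b|^p = 1}:
#' \eqn{4ab\,\Gamma(1+1/p)^2/\Gamma(1+2/p)}. Used as the analytic oracle for
#' the numerically integrated [section_properties()].
#'
#' @param a,b semiaxes, mm
#' @param p exponent (any real >= 1 accepted here)
#' @return area, mm^2
#' @export
superellipse_area <- function(a, b, p) {
  4 * a * b * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
}

#' Section properties by numeric integration
#'
#' Area, centroid and second moments of area of a cross-section profile,
#' computed with polygon (Green's theorem) formulas on a dense boundary
#' sampling. `Ix` is the second moment about the centroidal x axis
#' (integrand \eqn{y^2}, the bending axis of the coronal-plane load case);
#' `Iy` about the centroidal y axis. By symmetry of the two-half assembly the
#' centroid always lies on the x axis.
#'
#' @param cs a [cross_section()]
#' @param n number of boundary samples (default 2048); the inscribed-polygon
#'   O(n^-2) discretization error is removed by Richardson extrapolation
#'   against a 2n-gon
#' @return list with `area` (mm^2), `centroid` (c(x, y), mm), `Ix`, `Iy`
#'   (mm^4, about centroidal axes)
#' @export
section_properties <- function(cs, n = 2048) {
  if (!inherits(cs, "cross_section"))
    stop_stemopt("cs must be a cross_section", "invalid_parameter")
  at_n <- function(m) {
    th <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
    pts <- profile_point(cs, th)
    polygon_properties(pts[, 1], pts[, 2])
  }
  p1 <- at_n(n)
  p2 <- at_n(2L * n)
  rich <- function(a, b) b + (b - a) / 3
  list(area = rich(p1$area, p2$area),
       centroid = rich(p1$centroid, p2$centroid),
       Ix = rich(p1$Ix, p2$Ix),
       Iy = rich(p1$Iy, p2$Iy))
}

# Shoelace-type exact polygon formulas (counter-clockwise boundary).
polygon_properties <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  area <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * area)
  cy <- sum((y + yn) * cr) / (6 * area)
  ix0 <- sum((y^2 + y * yn + yn^2) * cr) / 12   # about origin x axis
  iy0 <- sum((x^2 + x * xn + xn^2) * cr) / 12
  list(area = area,
       centroid = c(x = cx, y = cy),
       Ix = ix0 - area * cy^2,
       Iy = iy0 - area * cx^2)
}

# ---------------------------------------------------------------------------
# design vector: 5 variable cross sections (stations 2-6) x (a1, a2, b, p)

#' Default design bounds for the 20-variable stem design vector
#'
#' Stations 2-6 each contribute (a1, a2, b, p). Exponent bounds follow the
#' published per-station table (station 1, the distal tip, is a fixed circle
#' and carries no variables). Semiaxis bounds are set so that, against the
#' default canal profile, the cement mantle thickness stays within the
#' admissible 2.0-3.0 mm band: per in-canal station the semiaxis range is
#' `canal radius - c(3, 2)` mm. Neck stations 5-6 (outside the cement) use
#' typical neck dimensions.
#'
#' @return a data.frame with columns `station`, `variable`, `lower`, `upper`,
#'   `integer` (one row per design variable, 20 rows), class `design_bounds`
#' @export
design_bounds <- function() {
  canal <- default_canal_radii()          # stations 1..4
  semi <- list(`2` = canal[2] - c(3, 2),
               `3` = canal[3] - c(3, 2),
               `4` = canal[4] - c(3, 2),
               `5` = c(6, 8),
               `6` = c(5, 7))
  pexp <- list(`2` = c(2, 3), `3` = c(2, 3), `4` = c(2, 4),
               `5` = c(2, 4), `6` = c(2, 3))
  rows <- lapply(2:6, function(s) {
    sr <- semi[[as.character(s)]]
    pr <- pexp[[as.character(s)]]
    data.frame(station = s,
               variable = c("a1", "a2", "b", "p"),
               lower = c(sr[1], sr[1], sr[1], pr[1]),
               upper = c(sr[2], sr[2], sr[2], pr[2]),
               integer = c(FALSE, FALSE, FALSE, TRUE))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("design_bounds", "data.frame")
  out
}

# Default circular canal radii at the in-bone stations 1..4 (mm).
# Station 1 leaves the fixed 6 mm distal circle a 2.5 mm mantle.
default_canal_radii <- function() c(8.5, 9, 10.5, 12.5)

#' Construct and validate a stem design vector
#'
#' @param values numeric vector of 20 values ordered station-major:
#'   (a1, a2, b, p) for stations 2, 3, 4, 5, 6
#' @param bounds a [design_bounds()] table
#' @return object of class `design_vector` with fields `values`, `bounds`,
#'   and `sections` (list of five [cross_section()] objects)
#' @export
design_vector <- function(values, bounds = design_bounds()) {
  if (length(values) != nrow(bounds))
    stop_stemopt(sprintf("design vector must have %d values, got %d",
                         nrow(bounds), length(values)), "constraint_error")
  bad <- which(values < bounds$lower - 1e-9 | values > bounds$upper + 1e-9)
  if (length(bad))
    stop_stemopt(paste0("design variables out of bounds: ",
                        paste(sprintf("station %d %s=%.4g not in [%g, %g]",
                                      bounds$station[bad],
                                      bounds$variable[bad], values[bad],
                                      bounds$lower[bad], bounds$upper[bad]),
                              collapse = "; ")),
                 "constraint_error")
  ip <- bounds$integer
  if (any(abs(values[ip] - round(values[ip])) > 1e-9))
    stop_stemopt("exponent variables must be integers", "constraint_error")
  sections <- lapply(seq(2, 6), function(s) {
    v <- values[bounds$station == s]
    names(v) <- bounds$variable[bounds$station == s]
    cross_section(v[["a1"]], v[["a2"]], v[["b"]], v[["p"]])
  })
  names(sections) <- paste0("station", 2:6)
  structure(list(values = values, bounds = bounds, sections = sections),
            class = "design_vector")
}

#' Midpoint design vector
#'
#' The design at the center of every search interval (exponents at the
#' integer floor of the midpoint). This is the package's documented default
#' stem: against the default canal it produces a uniform 2.5 mm cement
#' mantle.
#'
#' @param bounds a [design_bounds()] table
#' @return a [design_vector()]
#' @export
mid_design <- function(bounds = design_bounds()) {
  v <- (bounds$lower + bounds$upper) / 2
  v[bounds$integer] <- floor(v[bounds$integer])
  design_vector(v, bounds)
}

# ---------------------------------------------------------------------------
# skeleton and loft

#' Stem skeleton configuration
#'
#' Geometric layout of the stem: straight prosthesis axis (distal tip at
#' z = 0), neck axis in the coronal (y-z) plane, and a four-point Bezier
#' spline flushing the sharp axis-to-neck transition. Six key cross sections
#' ride on the skeleton: station 1 (fixed 6 mm circle) plus stations 2-3 are
#' normal to the prosthesis axis, station 4 is normal to the Bezier spline at
#' its midpoint, stations 5-6 are normal to the neck axis.
#'
#' Station and neck placements are not dictated by the methodology and are
#' exposed here with documented defaults: axis stations at fractions 0, 0.25
#' and 0.55 of the total length, Bezier endpoints `bezier_offset` mm from the
#' axis-neck junction with inner control points at 1/3 spacing, neck at 135
#' degrees to the prosthesis axis.
#'
#' @param total_length total stem length along axis + neck path, mm
#' @param axis_length length of the straight prosthesis axis (junction
#'   height), mm; the neck spans the remainder
#' @param neck_angle_deg angle between neck axis and prosthesis axis, degrees
#' @param distal_radius radius of the fixed circular distal section, mm
#' @param bezier_offset distance of the Bezier endpoints from the junction
#'   along each axis, mm
#' @param station_fractions fractions of `total_length` (along the axis)
#'   locating stations 1-3
#' @param neck_station_fractions fractions of the neck segment (beyond the
#'   Bezier endpoint) locating stations 5-6
#' @return object of class `stem_skeleton` with per-station centers, unit
#'   normals and local frames
#' @export
stem_skeleton <- function(total_length = 185, axis_length = 150,
                          neck_angle_deg = 135, distal_radius = 6,
                          bezier_offset = 25,
                          station_fractions = c(0, 0.25, 0.55),
                          neck_station_fractions = c(0.3, 1)) {
  if (axis_length <= 0 || total_length <= axis_length)
    stop_stemopt("need 0 < axis_length < total_length", "invalid_parameter")
  neck_length <- total_length - axis_length
  gamma <- deg2rad(180 - neck_angle_deg)
  junction <- c(0, 0, axis_length)
  neck_dir <- c(0, sin(gamma), cos(gamma))    # up and medial, coronal plane
  axis_dir <- c(0, 0, 1)

  # four-point Bezier across the junction
  p0 <- junction - bezier_offset * axis_dir
  p3 <- junction + bezier_offset * neck_dir
  ctrl <- rbind(p0, p0 + bezier_offset / 3 * axis_dir,
                p3 - bezier_offset / 3 * neck_dir, p3)

  bez <- function(t) {
    t(vapply(t, function(u) {
      w <- c((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
      colSums(ctrl * w)
    }, numeric(3)))
  }
  bez_tan <- function(t) {
    d <- t(vapply(t, function(u) {
      w <- 3 * c(-(1 - u)^2, (1 - u)^2 - 2 * u * (1 - u),
                 2 * u * (1 - u) - u^2, u^2)
      colSums(ctrl * w)
    }, numeric(3)))
    d / sqrt(rowSums(d^2))
  }

  centers <- rbind(
    station_fractions[1] * total_length * axis_dir,
    station_fractions[2] * total_length * axis_dir,
    station_fractions[3] * total_length * axis_dir,
    bez(0.5),
    junction + (bezier_offset +
      neck_station_fractions[1] * (neck_length - bezier_offset)) * neck_dir,
    junction + (bezier_offset +
      neck_station_fractions[2] * (neck_length - bezier_offset)) * neck_dir)
  normals <- rbind(axis_dir, axis_dir, axis_dir, bez_tan(0.5)[1, ],
                   neck_dir, neck_dir)
  rownames(centers) <- rownames(normals) <- paste0("station", 1:6)

  structure(list(total_length = total_length, axis_length = axis_length,
                 neck_length = neck_length,
                 neck_angle_deg = neck_angle_deg,
                 distal_radius = distal_radius,
                 bezier_control = ctrl, bezier = bez,
                 centers = centers, normals = normals),
            class = "stem_skeleton")
}

# Local in-plane frame of a station: e1 = global +x (a semiaxes), e2 = n x e1
station_frame <- function(normal) {
  e1 <- c(1, 0, 0)
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  e2 <- -e2 / sqrt(sum(e2^2))   # keep e2 with positive medial component
  if (e2[2] < 0) e2 <- -e2
  list(e1 = e1, e2 = e2)
}

#' Build the parametric stem model
#'
#' Assembles the six key cross sections (fixed distal circle plus the five
#' design sections) on the skeleton. The loft between stations is a cubic
#' spline interpolation of corresponding boundary points (natural cubic
#' splines in the axial direction through the six stations), evaluated by
#' [sample_surface()]. The construction is fully deterministic in its inputs.
#'
#' @param dv a [design_vector()]
#' @param skeleton a [stem_skeleton()]
#' @return object of class `stem_model`
#' @export
build_stem <- function(dv, skeleton = stem_skeleton()) {
  if (!inherits(dv, "design_vector"))
    stop_stemopt("dv must be a design_vector", "constraint_error")
  r <- skeleton$distal_radius
  sections <- c(list(station1 = cross_section(r, r, r, 2)), dv$sections)
  structure(list(skeleton = skeleton, sections = sections, dv = dv),
            class = "stem_model")
}

#' @export
print.stem_model <- function(x, ...) {
  cat(sprintf("stem_model: length %.0f mm, 6 stations, distal radius %.1f mm\n",
              x$skeleton$total_length, x$skeleton$distal_radius))
  invisible(x)
}

#' Sample the lofted stem surface
#'
#' Evaluates the spline loft on an `n_u` (along the stem path) by `n_v`
#' (around the profile) grid. Corresponding points of the six station
#' profiles (same parametric angle) are interpolated with natural cubic
#' splines in each coordinate against the cumulative center-line chord
#' length.
#'
#' @param stem a `stem_model` (from [build_stem()])
#' @param n_u axial resolution (>= 4)
#' @param n_v circumferential resolution (>= 4)
#' @return list with `points` (n_u x n_v x 3 array, mm), `u` (path
#'   parameter), `angles` (radians)
#' @export
sample_surface <- function(stem, n_u = 40, n_v = 32) {
  if (n_u < 4 || n_v < 4)
    stop_stemopt("surface sampling needs n_u >= 4 and n_v >= 4",
                 "invalid_parameter")
  sk <- stem$skeleton
  centers <- sk$centers
  d <- sqrt(rowSums(diff(centers)^2))
  u_st <- c(0, cumsum(d))
  u_st <- u_st / max(u_st)
  angles <- seq(0, 2 * pi, length.out = n_v + 1L)[-(n_v + 1L)]
  # station boundary points in 3D: 6 stations x n_v x 3
  st_pts <- array(NA_real_, c(6, n_v, 3))
  for (s in 1:6) {
    fr <- station_frame(sk$normals[s, ])
    loc <- profile_point(stem$sections[[s]], angles)
    for (k in 1:3)
      st_pts[s, , k] <- centers[s, k] + loc[, 1] * fr$e1[k] +
        loc[, 2] * fr$e2[k]
  }
  u <- seq(0, 1, length.out = n_u)
  pts <- array(NA_real_, c(n_u, n_v, 3))
  for (j in seq_len(n_v)) for (k in 1:3) {
    f <- stats::splinefun(u_st, st_pts[, j, k], method = "natural")
    pts[, j, k] <- f(u)
  }
  list(points = pts, u = u, angles = angles)
}

# ---------------------------------------------------------------------------
# STL export (ASCII), mesh volume, CSV profile export

#' Export the stem as a watertight STL mesh
#'
#' Triangulates the sampled loft surface and caps both ends with triangle
#' fans; the winding is oriented so that facet normals point outward
#' (positive enclosed volume). The mesh is written as ASCII STL.
#'
#' @param stem a `stem_model` (from [build_stem()]) (or the result of [sample_surface()])
#' @param path output file path
#' @param n_u,n_v sampling resolution when `stem` is a model
#' @return invisibly, the triangle array (n_tri x 3 x 3)
#' @export
export_stl <- function(stem, path, n_u = 60, n_v = 48) {
  surf <- if (inherits(stem, "stem_model"))
    sample_surface(stem, n_u, n_v) else stem
  tri <- triangulate_loft(surf$points)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_stemopt(
                    paste("cannot open STL output:", conditionMessage(e)),
                    "file_error"))
  on.exit(close(con))
  writeLines("solid stem", con)
  n <- dim(tri)[1]
  v1 <- tri[, 1, , drop = FALSE]; dim(v1) <- c(n, 3)
  v2 <- tri[, 2, , drop = FALSE]; dim(v2) <- c(n, 3)
  v3 <- tri[, 3, , drop = FALSE]; dim(v3) <- c(n, 3)
  e1 <- v2 - v1; e2 <- v3 - v1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nl <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  txt <- sprintf(
    paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
           "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
           "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
    nx / nl, ny / nl, nz / nl,
    v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
    v3[, 1], v3[, 2], v3[, 3])
  writeLines(txt, con)
  writeLines("endsolid stem", con)
  invisible(tri)
}

# Grid (n_u x n_v x 3) -> closed triangle soup with end caps, wound so
# that facet normals point outward (positive enclosed volume).
triangulate_loft <- function(pts) {
  n_u <- dim(pts)[1]; n_v <- dim(pts)[2]
  tris <- vector("list", 2 * (n_u - 1) * n_v + 2 * n_v)
  idx <- 1L
  nxt <- c(seq_len(n_v)[-1], 1L)
  for (i in seq_len(n_u - 1)) for (j in seq_len(n_v)) {
    jn <- nxt[j]
    a <- pts[i, j, ]; b <- pts[i + 1, j, ]
    cc <- pts[i + 1, jn, ]; d <- pts[i, jn, ]
    # wound so the normal points radially outward (CCW angles, +z axial)
    tris[[idx]] <- rbind(a, cc, b); idx <- idx + 1L
    tris[[idx]] <- rbind(a, d, cc); idx <- idx + 1L
  }
  c0 <- colMeans(pts[1, , ]); c1 <- colMeans(pts[n_u, , ])
  for (j in seq_len(n_v)) {
    jn <- nxt[j]
    tris[[idx]] <- rbind(c0, pts[1, jn, ], pts[1, j, ]); idx <- idx + 1L
    tris[[idx]] <- rbind(c1, pts[n_u, j, ], pts[n_u, jn, ]); idx <- idx + 1L
  }
  out <- array(NA_real_, c(length(tris), 3, 3))
  for (t in seq_along(tris)) out[t, , ] <- tris[[t]]
  if (mesh_volume(out) < 0) out <- out[, c(1, 3, 2), , drop = FALSE]
  out
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-oriented closed meshes.
#'
#' @param tri triangle array (n_tri x 3 vertices x 3 coords)
#' @return volume, mm^3
#' @export
mesh_volume <- function(tri) {
  v1 <- tri[, 1, ]; v2 <- tri[, 2, ]; v3 <- tri[, 3, ]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Read an ASCII STL file
#'
#' @param path STL file path
#' @return triangle array (n_tri x 3 x 3)
#' @export
read_stl_ascii <- function(path) {
  if (!file.exists(path)) stop_stemopt("STL file not found", "file_error")
  ln <- readLines(path)
  vx <- grep("^\\s*vertex", ln, value = TRUE)
  m <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"),
                             function(f) as.numeric(f[2:4])))
  if (nrow(m) %% 3 != 0)
    stop_stemopt("malformed ASCII STL: vertex count not divisible by 3",
                 "file_error")
  n <- nrow(m) / 3
  tri <- array(NA_real_, c(n, 3, 3))
  for (k in 1:3) tri[, k, ] <- m[seq(k, nrow(m), by = 3), ]
  tri
}

#' Export station profiles as CSV
#'
#' Writes one row per (station, angle) with the 3D boundary point, the
#' standard exchange format for downstream CAD/FE tooling.
#'
#' @param stem a `stem_model` (from [build_stem()])
#' @param path output CSV path
#' @param n_v samples per profile
#' @return invisibly, the exported data.frame
#' @export
export_profiles_csv <- function(stem, path, n_v = 64) {
  sk <- stem$skeleton
  angles <- seq(0, 2 * pi, length.out = n_v + 1L)[-(n_v + 1L)]
  rows <- lapply(1:6, function(s) {
    fr <- station_frame(sk$normals[s, ])
    loc <- profile_point(stem$sections[[s]], angles)
    p3 <- t(sk$centers[s, ] + t(loc[, 1] %o% fr$e1 + loc[, 2] %o% fr$e2))
    data.frame(station_id = s, angle_rad = angles,
               x = p3[, 1], y = p3[, 2], z = p3[, 3])
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

# ---------------------------------------------------------------------------
# cement mantle sections and admissibility constraints

#' Default canal profile for the cement mantle check
#'
#' Circular canal cross sections at the four in-bone stations (the distal
#' tip and stations 2-4). The radii are chosen so the midpoint design
#' ([mid_design()]) leaves a uniform 2.5 mm cement mantle.
#'
#' @return list of four [cross_section()] objects (stations 1-4)
#' @export
canal_profile <- function() {
  lapply(default_canal_radii(), function(r) cross_section(r, r, r, 2))
}

#' Cement ring geometry at the in-bone stations
#'
#' Radial cement thickness (canal radius minus stem radius along each ray
#' from the shared center) as a function of angle, per station.
#'
#' @param stem a `stem_model` (from [build_stem()])
#' @param canal list of canal [cross_section()]s (stations 1..length(canal))
#' @param n_angle angular resolution
#' @param rotation rigid rotation (radians) applied to stem and canal
#'   together; thickness extrema are invariant under it
#' @return list per station: `angle`, `thickness` (mm), `min`, `max`
#' @export
cement_sections <- function(stem, canal = canal_profile(), n_angle = 720,
                            rotation = 0) {
  phi <- seq(0, 2 * pi, length.out = n_angle + 1L)[-(n_angle + 1L)]
  lapply(seq_along(canal), function(s) {
    r_c <- superellipse_radius(canal[[s]], phi - rotation)
    r_s <- superellipse_radius(stem$sections[[s]], phi - rotation)
    thk <- r_c - r_s
    if (any(thk <= 0))
      stop_stemopt(sprintf(
        "stem boundary outside or touching canal at station %d", s),
        "geometry_violation")
    list(station = s, angle = phi, thickness = thk,
         min = min(thk), max = max(thk))
  })
}

#' Clinical admissibility check of a stem design
#'
#' A design is admissible when (a) the cement mantle thickness at every
#' in-bone station stays within `[t_min, t_max]` (defaults 2.0 and 3.0 mm),
#' (b) the stem boundary stays strictly inside the canal at every angle,
#' and (c) the insertability taper rule holds: cross-section areas are
#' monotone nonincreasing from the proximal station 4 down to the distal
#' tip (no distal bulge). The thickness band is measured along the
#' principal semiaxis directions (anterior, posterior, medial, lateral
#' rays), mirroring how the semiaxis search bounds enforce the band; a
#' trapezoidal section (p > 2) legitimately runs closer to a circular
#' canal toward its corners, which the full-containment check (b) still
#' guards. The taper rule is this package's operational reading of
#' "clinically admissible" and can be switched off.
#'
#' @param dv a [design_vector()]
#' @param canal canal profile as in [cement_sections()]
#' @param t_min,t_max admissible cement thickness band, mm
#' @param taper_rule apply the monotone-taper rule?
#' @param skeleton skeleton used to place the fixed distal section
#' @param n_angle angular resolution of the containment scan
#' @return object of class `constraint_report`: fields `admissible`,
#'   `violations` (character vector), `min_cement_thickness`,
#'   `max_cement_thickness` (extrema over the principal rays),
#'   `violation_magnitude` (total mm overshoot)
#' @export
check_constraints <- function(dv, canal = canal_profile(), t_min = 2,
                              t_max = 3, taper_rule = TRUE,
                              skeleton = stem_skeleton(), n_angle = 360) {
  stem <- build_stem(dv, skeleton)
  violations <- character(0)
  mag <- 0
  rays <- c(0, pi / 2, pi, 3 * pi / 2)
  contained <- tryCatch({cement_sections(stem, canal, n_angle); TRUE},
                        stemopt_error = function(e) FALSE)
  thk <- unlist(lapply(seq_along(canal), function(s) {
    superellipse_radius(canal[[s]], rays) -
      superellipse_radius(stem$sections[[s]], rays)
  }))
  tmin_all <- min(thk); tmax_all <- max(thk)
  if (!contained) {
    violations <- c(violations, "stem_outside_canal")
    mag <- mag + t_min
  }
  if (tmin_all < t_min) {
    violations <- c(violations, "cement_too_thin")
    mag <- mag + (t_min - tmin_all)
  }
  if (tmax_all > t_max) {
    violations <- c(violations, "cement_too_thick")
    mag <- mag + (tmax_all - t_max)
  }
  if (taper_rule) {
    areas <- vapply(stem$sections[1:4],
                    function(cs) section_properties(cs, n = 512)$area,
                    numeric(1))
    if (any(diff(areas) < -1e-9)) {
      violations <- c(violations, "distal_bulge")
      mag <- mag + max(0, max(-diff(areas)) / 100)
    }
  }
  structure(list(admissible = length(violations) == 0L,
                 violations = violations,
                 min_cement_thickness = tmin_all,
                 max_cement_thickness = tmax_all,
                 violation_magnitude = mag),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("constraint_report: %s (cement %.2f-%.2f mm)\n",
              if (x$admissible) "admissible" else
                paste("violations:", paste(x$violations, collapse = ", ")),
              x$min_cement_thickness, x$max_cement_thickness))
  invisible(x)
}
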