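# Composite-beam structural surrogate of the femur-cement-implant assembly.
#
# The femur is an Euler-Bernoulli cortical tube fixed at its distal end
# (z = 0) and loaded at the proximal end by the hip joint contact force and
# the abductor muscle force, both acting in the coronal (y-z) plane. Over
# the implanted span the section is a fully bonded three-material composite
# (bone annulus, cement ring, stem); strain compatibility gives a common
# axial strain and curvature per section, and per-material stress
# sigma = E (eps0 + kappa * y). The walking load oscillates between zero and
# its full value (R = 0 cycle), so the equivalent alternating and mean
# stresses both equal half the peak magnitude.

#' Walking load case
#'
#' Joint contact force applied at the (medially offset) femoral head and
#' abductor muscle force at the (laterally offset) greater trochanter, both
#' in the coronal plane at the configured angles from the femur axis, plus
#' bodyweight for reference. Defaults: 2.5 kN joint force at 10 degrees,
#' 1.5 kN abductor force at 15 degrees, bodyweight 700 N (3.5x bodyweight
#' loading in total).
#'
#' @param joint_kn joint contact force magnitude, kN
#' @param joint_angle_deg joint force angle from the femur axis, degrees
#' @param abductor_kn abductor force magnitude, kN
#' @param abductor_angle_deg abductor force angle from the femur axis, degrees
#' @param bodyweight_n bodyweight, N
#' @param joint_offset_mm medial (+y) lever arm of the joint force, mm
#' @param abductor_offset_mm lateral (-y) lever arm of the abductor force,
#'   mm (given as a positive number)
#' @return object of class `load_case`
#' @export
load_case <- function(joint_kn = 2.5, joint_angle_deg = 10,
                      abductor_kn = 1.5, abductor_angle_deg = 15,
                      bodyweight_n = 700, joint_offset_mm = 45,
                      abductor_offset_mm = 45) {
  if (joint_kn < 0 || abductor_kn < 0)
    stop_stemopt("force magnitudes must be nonnegative", "invalid_parameter")
  structure(list(joint_kn = joint_kn, joint_angle_deg = joint_angle_deg,
                 abductor_kn = abductor_kn,
                 abductor_angle_deg = abductor_angle_deg,
                 bodyweight_n = bodyweight_n,
                 joint_offset_mm = joint_offset_mm,
                 abductor_offset_mm = abductor_offset_mm),
            class = "load_case")
}

# Point loads (N, mm) in the coronal plane: columns y (offset), z
# (application height), fy, fz. The joint force presses the head downward
# and slightly laterally; the abductor pulls the trochanter up and medially.
load_points <- function(loads, femur_length) {
  aj <- deg2rad(loads$joint_angle_deg)
  aa <- deg2rad(loads$abductor_angle_deg)
  rbind(
    c(y = loads$joint_offset_mm, z = femur_length,
      fy = -1000 * loads$joint_kn * sin(aj),
      fz = -1000 * loads$joint_kn * cos(aj)),
    c(y = -loads$abductor_offset_mm, z = femur_length,
      fy = 1000 * loads$abductor_kn * sin(aa),
      fz = 1000 * loads$abductor_kn * cos(aa)))
}

# Internal section resultants at height z: axial force N (N) and coronal
# bending moment M (N mm) from all loads applied above z.
section_forces <- function(loads, femur_length, z) {
  lp <- load_points(loads, femur_length)
  N <- numeric(length(z))
  M <- numeric(length(z))
  for (r in seq_len(nrow(lp))) {
    above <- unname(lp[r, "z"] > z)
    N <- N + above * lp[[r, "fz"]]
    M <- M + above * ((lp[[r, "z"]] - z) * lp[[r, "fy"]] -
                      lp[[r, "y"]] * lp[[r, "fz"]])
  }
  list(N = unname(N), M = unname(M))
}

#' Surrogate femur geometry
#'
#' A cortical tube described by per-station outer and canal radii (linearly
#' interpolated between stations), standing in for an image- or
#' library-based femur model. The default emulates an adult THA femur:
#' 25 mm shaft diameter flaring to 33 mm proximally, canal narrowest at the
#' isthmus (8.5 mm radius, where the stem tip sits) and flaring to 12.5 mm
#' at the resection plane, cortical wall ~3.5-4 mm throughout.
#'
#' @param length femur model length, mm
#' @param z_stations heights of the radius stations, mm (increasing)
#' @param outer_r outer radius per station, mm
#' @param canal_r canal radius per station, mm (0 = solid section)
#' @param bone bone [material()]
#' @return object of class `surrogate_femur`
#' @export
surrogate_femur <- function(length = 400,
                            z_stations = c(0, 250, 296.25, 351.75, 400),
                            outer_r = c(12.5, 12.5, 12.5, 14.1, 16.5),
                            canal_r = c(9.5, 8.5, 9, 10.5, 12.5),
                            bone = builtin_catalog("bone")) {
  if (length <= 0) stop_stemopt("femur length must be positive",
                                "invalid_parameter")
  if (base::length(z_stations) != base::length(outer_r) ||
      base::length(z_stations) != base::length(canal_r))
    stop_stemopt("z_stations, outer_r and canal_r must have equal length",
                 "invalid_parameter")
  if (any(diff(z_stations) <= 0))
    stop_stemopt("z_stations must be strictly increasing", "invalid_parameter")
  if (any(canal_r < 0) || any(outer_r <= canal_r))
    stop_stemopt("need outer_r > canal_r >= 0 at every station",
                 "invalid_parameter")
  structure(list(length = length, z_stations = z_stations,
                 outer_r = outer_r, canal_r = canal_r, bone = bone),
            class = "surrogate_femur")
}

#' @export
print.surrogate_femur <- function(x, ...) {
  cat(sprintf("surrogate_femur: L = %.0f mm, outer %.1f-%.1f mm, canal %.1f-%.1f mm\n",
              x$length, min(x$outer_r), max(x$outer_r),
              min(x$canal_r), max(x$canal_r)))
  invisible(x)
}

femur_outer_r <- function(femur, z) interp1(femur$z_stations, femur$outer_r, z)
femur_canal_r <- function(femur, z) interp1(femur$z_stations, femur$canal_r, z)

# Shared sampling grid: axial cell centers x uniform circumferential angles.
surface_grid <- function(femur, n_axial, n_circ) {
  z <- (seq_len(n_axial) - 0.5) / n_axial * femur$length
  phi <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  list(z = z, phi = phi, n_axial = n_axial, n_circ = n_circ)
}

stress_samples_frame <- function(grid, femur, sigma) {
  df <- data.frame(
    location_id = seq_len(grid$n_axial * grid$n_circ),
    axial = rep(seq_len(grid$n_axial), each = grid$n_circ),
    circ = rep(seq_len(grid$n_circ), times = grid$n_axial),
    z_mm = rep(grid$z, each = grid$n_circ),
    angle_rad = rep(grid$phi, times = grid$n_axial),
    sigma_mpa = sigma)
  attr(df, "n_axial") <- grid$n_axial
  attr(df, "n_circ") <- grid$n_circ
  attr(df, "femur_length") <- femur$length
  class(df) <- c("stress_samples", "data.frame")
  df
}

#' Bone-surface stresses of the intact femur
#'
#' Euler-beam solution on the cortical tube: equivalent alternating stress
#' (half the peak uniaxial magnitude of axial + bending stress, see the
#' R = 0 cycle convention) at every grid location on the external surface.
#'
#' @param femur a [surrogate_femur()]
#' @param loads a [load_case()]
#' @param n_axial,n_circ sampling grid (defaults 95 x 32 = 3040 locations)
#' @return object of class `stress_samples`: a data.frame with columns
#'   `location_id`, `axial`, `circ`, `z_mm`, `angle_rad`, `sigma_mpa`
#' @export
solve_intact <- function(femur, loads, n_axial = 95, n_circ = 32) {
  if (n_axial < 4 || n_circ < 4)
    stop_stemopt("grid must be at least 4 x 4", "invalid_parameter")
  grid <- surface_grid(femur, n_axial, n_circ)
  ro <- femur_outer_r(femur, grid$z)
  rc <- femur_canal_r(femur, grid$z)
  if (any(ro <= rc))
    stop_stemopt("degenerate femur section (outer <= canal)",
                 "singular_section")
  A <- pi * (ro^2 - rc^2)
  I <- pi / 4 * (ro^4 - rc^4)
  sf <- section_forces(loads, femur$length, grid$z)
  # expand to grid (circ fastest, matching stress_samples_frame)
  y <- rep(ro, each = grid$n_circ) * rep(cos(grid$phi), times = n_axial)
  sig_peak <- rep(sf$N / A, each = grid$n_circ) +
    rep(sf$M / I, each = grid$n_circ) * y
  stress_samples_frame(grid, femur, abs(sig_peak) / 2)
}

# ---------------------------------------------------------------------------
# implanted assembly

#' Assemble the implanted femur model
#'
#' Places the stem in the femur with its distal tip at
#' `femur$length - axis_length` so the straight axis portion spans the
#' proximal femur up to the resection plane; the cement fills the canal
#' around the stem. Stem section properties are interpolated linearly in z
#' between the four in-bone stations (the proximal station 4 is projected
#' onto the resection plane for the 1D solver). The stem material is either
#' a homogeneous [material()] or an [fgm_layout()].
#'
#' @param dv a [design_vector()] (or a `stem_model` (from [build_stem()]))
#' @param femur a [surrogate_femur()]
#' @param stem_material a [material()] or [fgm_layout()]
#' @param cement cement [material()]
#' @param skeleton a [stem_skeleton()]
#' @return object of class `implant_assembly`
#' @export
implant_assembly <- function(dv, femur = surrogate_femur(),
                             stem_material = builtin_catalog("ti6al4v"),
                             cement = builtin_catalog("pmma"),
                             skeleton = stem_skeleton()) {
  stem <- if (inherits(dv, "stem_model")) dv else build_stem(dv, skeleton)
  sk <- stem$skeleton
  ax <- sk$axis_length
  z0 <- femur$length - ax
  if (z0 < 0)
    stop_stemopt("stem axis longer than femur model", "constraint_error")
  # in-bone stations: 1-3 at their axial positions, 4 projected to the top
  s_local <- c(sk$centers[1:3, 3], ax)
  props <- lapply(stem$sections[1:4], section_properties, n = 1024)
  st <- list(z = z0 + s_local,
             area = vapply(props, `[[`, numeric(1), "area"),
             Ix = vapply(props, `[[`, numeric(1), "Ix"))
  structure(list(stem = stem, femur = femur, stem_material = stem_material,
                 cement = cement, z0 = z0, stations = st,
                 span = c(z0, femur$length)),
            class = "implant_assembly")
}

stem_area_at <- function(assembly, z)
  interp1(assembly$stations$z, assembly$stations$area, z)
stem_Ix_at <- function(assembly, z)
  interp1(assembly$stations$z, assembly$stations$Ix, z)

stem_modulus_mpa <- function(assembly, z) {
  m <- assembly$stem_material
  if (inherits(m, "fgm_layout"))
    1000 * modulus_at(m, z - assembly$z0)
  else
    rep(1000 * m$modulus_gpa, length(z))
}

# polar radius of the stem boundary at femur height z (linear interpolation
# of the station radii), used to place cement mid-thickness nodes
stem_radius_at <- function(assembly, z, phi) {
  zs <- assembly$stations$z
  r_st <- vapply(assembly$stem$sections[1:4], superellipse_radius,
                 numeric(length(phi)), phi = phi)
  if (length(phi) == 1L) r_st <- matrix(r_st, nrow = 1L)
  i <- findInterval(clamp(z, zs[1], zs[4]), zs, rightmost.closed = TRUE)
  i <- clamp(i, 1L, 3L)
  w <- (z - zs[i]) / (zs[i + 1L] - zs[i])
  r_st[, i] * (1 - w) + r_st[, i + 1L] * w
}

#' Solve the implanted femur-cement-implant assembly
#'
#' Transformed-section (strain-compatibility) composite beam over the
#' implanted span, plain cortical tube elsewhere. Returns bone-surface
#' stresses on the same grid as [solve_intact()] and the cement stress
#' field at ring mid-thickness nodes (alternating and mean components from
#' the R = 0 cycle convention: both equal half the peak magnitude).
#'
#' @param assembly an [implant_assembly()]
#' @param loads a [load_case()]
#' @param n_axial,n_circ sampling grid (defaults 95 x 32)
#' @return list with `bone` (a `stress_samples` data.frame carrying an
#'   `in_span` column) and `cement` (a `cement_stress_field`: data.frame
#'   with `node_id`, `z_mm`, `angle_rad`, `sigma_a_mpa`, `sigma_m_mpa`)
#' @export
solve_implanted <- function(assembly, loads, n_axial = 95, n_circ = 32) {
  femur <- assembly$femur
  grid <- surface_grid(femur, n_axial, n_circ)
  ro <- femur_outer_r(femur, grid$z)
  rc <- femur_canal_r(femur, grid$z)
  sf <- section_forces(loads, femur$length, grid$z)
  E_b <- 1000 * femur$bone$modulus_gpa
  E_c <- 1000 * assembly$cement$modulus_gpa
  in_span <- grid$z >= assembly$span[1] & grid$z <= assembly$span[2]

  eps0 <- numeric(length(grid$z))
  kap <- numeric(length(grid$z))
  # outside the span: equivalent homogeneous tube
  A_t <- pi * (ro^2 - rc^2)
  I_t <- pi / 4 * (ro^4 - rc^4)
  eps0[!in_span] <- sf$N[!in_span] / (E_b * A_t[!in_span])
  kap[!in_span] <- sf$M[!in_span] / (E_b * I_t[!in_span])

  if (any(in_span)) {
    zi <- grid$z[in_span]
    A_s <- stem_area_at(assembly, zi)
    I_s <- stem_Ix_at(assembly, zi)
    E_s <- stem_modulus_mpa(assembly, zi)
    A_canal <- pi * rc[in_span]^2
    I_canal <- pi / 4 * rc[in_span]^4
    if (any(A_s >= A_canal))
      stop_stemopt("stem section exceeds canal inside the implanted span",
                   "geometry_violation")
    A_cem <- A_canal - A_s
    I_cem <- I_canal - I_s
    EA <- E_b * A_t[in_span] + E_c * A_cem + E_s * A_s
    EI <- E_b * I_t[in_span] + E_c * I_cem + E_s * I_s
    eps0[in_span] <- sf$N[in_span] / EA
    kap[in_span] <- sf$M[in_span] / EI
  }

  y <- rep(ro, each = grid$n_circ) * rep(cos(grid$phi), times = n_axial)
  sig_peak <- E_b * (rep(eps0, each = grid$n_circ) +
                     rep(kap, each = grid$n_circ) * y)
  bone <- stress_samples_frame(grid, femur, abs(sig_peak) / 2)
  bone$in_span <- rep(in_span, each = grid$n_circ)

  # cement nodes: every in-span axial row, mid-thickness radius
  zi <- grid$z[in_span]
  eps_i <- eps0[in_span]
  kap_i <- kap[in_span]
  rc_i <- rc[in_span]
  nseg <- length(zi)
  r_mid <- matrix(NA_real_, nrow = grid$n_circ, ncol = nseg)
  for (k in seq_len(nseg))
    r_mid[, k] <- (stem_radius_at(assembly, zi[k], grid$phi) + rc_i[k]) / 2
  y_c <- r_mid * cos(grid$phi)       # column-wise recycling over phi
  sig_c <- abs(E_c * (rep(eps_i, each = grid$n_circ) +
                      rep(kap_i, each = grid$n_circ) * as.vector(y_c)))
  cement <- data.frame(
    node_id = seq_len(nseg * grid$n_circ),
    z_mm = rep(zi, each = grid$n_circ),
    angle_rad = rep(grid$phi, times = nseg),
    sigma_a_mpa = sig_c / 2,
    sigma_m_mpa = sig_c / 2)
  class(cement) <- c("cement_stress_field", "data.frame")

  list(bone = bone, cement = cement)
}

# ---------------------------------------------------------------------------
# stress-field exchange (lets external 3D FE results replace the surrogate)

#' Export a stress field to CSV
#'
#' @param field a `stress_samples` or `cement_stress_field` data.frame
#' @param path output CSV path
#' @return invisibly, `field`
#' @export
export_stress_field <- function(field, path) {
  df <- as.data.frame(field)
  if (inherits(field, "stress_samples")) {
    df$n_axial <- attr(field, "n_axial")
    df$n_circ <- attr(field, "n_circ")
    df$femur_length <- attr(field, "femur_length")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(field)
}

#' Import a stress field from CSV
#'
#' Validates the declared schema and the nonnegativity of stresses.
#' Surface fields require columns `location_id, axial, circ, z_mm,
#' angle_rad, sigma_mpa`; cement fields require `node_id, z_mm, angle_rad,
#' sigma_a_mpa, sigma_m_mpa`.
#'
#' @param path CSV file path
#' @param type `"surface"` or `"cement"`
#' @return a `stress_samples` or `cement_stress_field` data.frame
#' @export
import_stress_field <- function(path, type = c("surface", "cement")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_stemopt("stress-field file not found",
                                       "file_error")
  df <- utils::read.csv(path)
  need <- if (type == "surface")
    c("location_id", "axial", "circ", "z_mm", "angle_rad", "sigma_mpa")
  else
    c("node_id", "z_mm", "angle_rad", "sigma_a_mpa", "sigma_m_mpa")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_stemopt(paste0("stress-field CSV missing column(s): ",
                        paste(miss, collapse = ", ")), "parse_error")
  sig_cols <- grep("^sigma", need, value = TRUE)
  for (cc in sig_cols) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] < 0)
    if (length(bad))
      stop_stemopt(sprintf(
        "invalid stress in column %s at row %d (must be finite and >= 0)",
        cc, bad[1]), "validation_error")
  }
  out <- df[need]
  if (type == "surface") {
    attr(out, "n_axial") <- if ("n_axial" %in% names(df)) df$n_axial[1] else
      length(unique(df$axial))
    attr(out, "n_circ") <- if ("n_circ" %in% names(df)) df$n_circ[1] else
      length(unique(df$circ))
    if ("femur_length" %in% names(df))
      attr(out, "femur_length") <- df$femur_length[1]
    class(out) <- c("stress_samples", "data.frame")
  } else {
    class(out) <- c("cement_stress_field", "data.frame")
  }
  out
}
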