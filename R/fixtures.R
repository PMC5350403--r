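# Deterministic generators of surrogate femurs, stress-sample pairs and
# cement stress fields with known ground truth, so every module can be
# exercised without any external data. All generators are pure functions of
# their parameters and seed.

#' Generate a surrogate femur
#'
#' Constant-radius tube by default; `taper > 0` widens both radii linearly
#' toward the proximal end.
#'
#' @param outer_radius distal outer radius, mm
#' @param canal_radius distal canal radius, mm (must be < outer_radius)
#' @param length femur length, mm
#' @param taper proximal radial widening, mm (applied to both radii)
#' @param seed unused placeholder kept for generator-signature uniformity
#' @return a [surrogate_femur()]
#' @export
make_surrogate_femur <- function(outer_radius = 12.5, canal_radius = 9,
                                 length = 400, taper = 0, seed = 1) {
  surrogate_femur(length = length, z_stations = c(0, length),
                  outer_r = c(outer_radius, outer_radius + taper),
                  canal_r = c(canal_radius, canal_radius + taper))
}

#' Generate an aligned intact/implanted stress-sample pair
#'
#' The intact field is a smooth positive stress pattern; the implanted
#' field applies a known per-location fractional reduction plus optional
#' multiplicative noise, giving a ground-truth fixture for the stress
#' shielding coefficient.
#'
#' @param n_axial,n_circ grid size
#' @param reduction fractional stress reduction, either a scalar or a
#'   per-axial-station vector (0 = no shielding)
#' @param noise multiplicative noise standard deviation on the implanted
#'   field
#' @param seed RNG seed
#' @param base_stress mean level of the intact field, MPa
#' @return list with `intact` and `implanted` `stress_samples` data.frames
#' @export
make_stress_pair <- function(n_axial = 20, n_circ = 16, reduction = 0.45,
                             noise = 0, seed = 1, base_stress = 20) {
  set.seed(seed)
  femur <- make_surrogate_femur(length = 400)
  grid <- surface_grid(femur, n_axial, n_circ)
  sig <- base_stress *
    (1 + 0.5 * sin(rep(grid$z, each = n_circ) / 400 * pi) *
       cos(rep(grid$phi, times = n_axial)))^2
  sig <- sig + 1e-3                      # keep strictly positive
  intact <- stress_samples_frame(grid, femur, sig)
  red <- if (length(reduction) == 1L) rep(reduction, n_axial) else reduction
  if (length(red) != n_axial)
    stop_stemopt("reduction must be scalar or one value per axial station",
                 "invalid_parameter")
  fac <- (1 - rep(red, each = n_circ)) *
    (1 + noise * stats::rnorm(n_axial * n_circ))
  implanted <- stress_samples_frame(grid, femur, pmax(sig * fac, 0))
  list(intact = intact, implanted = implanted)
}

#' Generate a cement stress field with a controllable damaged fraction
#'
#' Draws node stresses from a log-uniform range; when `n_damaged` is given,
#' exactly that many nodes receive an equivalent stress above the S-N
#' stress at `design_life` (life strictly shorter than the design life)
#' and all others strictly below it, so the damage parameter recovers
#' `100 * n_damaged / imax` exactly. Mean stresses are zero so the Goodman
#' correction is the identity and the planted lives are exact.
#'
#' @param imax number of cement nodes
#' @param sigma_range stress amplitude range, MPa (log-uniform draw)
#' @param n_damaged optional exact number of nodes with life below
#'   `design_life`
#' @param curve the [sn_curve()] the damaged fraction is planted against
#' @param design_life design life used for planting, cycles
#' @param seed RNG seed
#' @return a `cement_stress_field` data.frame
#' @export
make_cement_field <- function(imax = 1000, sigma_range = c(1, 50),
                              n_damaged = NULL, curve = sn_curve(),
                              design_life = 2e6, seed = 1) {
  set.seed(seed)
  if (imax < 1) stop_stemopt("imax must be >= 1", "invalid_parameter")
  sig <- exp(stats::runif(imax, log(sigma_range[1]), log(sigma_range[2])))
  if (!is.null(n_damaged)) {
    if (n_damaged < 0 || n_damaged > imax)
      stop_stemopt("n_damaged must lie in [0, imax]", "invalid_parameter")
    s_crit <- sn_stress(curve, design_life)
    idx <- sample.int(imax, n_damaged)
    sig[] <- s_crit * stats::runif(imax, 0.5, 0.95)       # all safe
    sig[idx] <- s_crit * stats::runif(n_damaged, 1.05, 1.5) # exactly these fail
  }
  out <- data.frame(node_id = seq_len(imax),
                    z_mm = stats::runif(imax, 250, 400),
                    angle_rad = stats::runif(imax, 0, 2 * pi),
                    sigma_a_mpa = sig,
                    sigma_m_mpa = 0)
  class(out) <- c("cement_stress_field", "data.frame")
  out
}
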