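# Stress-life fatigue assessment of the cement mantle: Goodman mean-stress
# correction, power-law S-N life, binary nodal damage, and the critical
# cement damage accumulation parameter (percentage of cement nodes whose
# fatigue life falls short of the design life).

#' Power-law S-N curve
#'
#' Log-log linear stress-life model `S = A * N^b` with a valid cycle range;
#' stresses below the curve at `n_max` are treated as runout. The default
#' coefficients are a log-log linear fit consistent with published
#' tension-tension fatigue data for PMMA bone cement (A = 90 MPa,
#' b = -0.13; S at 2e6 cycles ~ 13.7 MPa). Results always carry the curve
#' used.
#'
#' @param a_mpa curve coefficient A, MPa (> 0)
#' @param b curve exponent (< 0)
#' @param n_min,n_max valid cycle range
#' @return object of class `sn_curve`
#' @export
sn_curve <- function(a_mpa = 90, b = -0.13, n_min = 1e2, n_max = 1e8) {
  if (!is_number(a_mpa) || a_mpa <= 0)
    stop_stemopt("S-N coefficient A must be positive", "invalid_parameter")
  if (!is_number(b) || b >= 0)
    stop_stemopt("S-N exponent b must be negative", "invalid_parameter")
  if (n_min <= 0 || n_max <= n_min)
    stop_stemopt("need 0 < n_min < n_max", "invalid_parameter")
  structure(list(a_mpa = a_mpa, b = b, n_min = n_min, n_max = n_max),
            class = "sn_curve")
}

#' @export
print.sn_curve <- function(x, ...) {
  cat(sprintf("sn_curve: S = %.4g * N^%.4g MPa, valid %.3g-%.3g cycles\n",
              x$a_mpa, x$b, x$n_min, x$n_max))
  invisible(x)
}

#' Stress amplitude at a given life (forward S-N evaluation)
#'
#' @param curve an [sn_curve()]
#' @param n cycles
#' @return fully reversed stress amplitude, MPa
#' @export
sn_stress <- function(curve, n) curve$a_mpa * n^curve$b

#' Goodman mean-stress correction
#'
#' Converts an (amplitude, mean) stress pair to the equivalent fully
#' reversed amplitude `sigma_a / (1 - sigma_m / sigma_u)`.
#'
#' @param sigma_a alternating stress amplitude, MPa (>= 0)
#' @param sigma_m mean stress, MPa (0 <= sigma_m < sigma_u)
#' @param sigma_u ultimate strength, MPa
#' @return equivalent fully reversed amplitude, MPa (vectorized)
#' @export
goodman_correct <- function(sigma_a, sigma_m, sigma_u) {
  if (any(sigma_a < 0))
    stop_stemopt("alternating stress must be nonnegative", "invalid_parameter")
  if (any(sigma_m < 0))
    stop_stemopt("mean stress must be nonnegative", "invalid_parameter")
  if (any(sigma_m >= sigma_u))
    stop_stemopt("mean stress at or above ultimate strength: no finite life",
                 "infinite_life_violation")
  sigma_a / (1 - sigma_m / sigma_u)
}

#' Cycles to failure from the S-N curve
#'
#' Inverts `S = A * N^b`: `N = (sigma_eq / A)^(1/b)`, clamped to the
#' curve's valid cycle range. Stresses below the runout stress map to
#' `n_max` (runout); stresses above the curve at `n_min` map to `n_min`.
#'
#' @param sigma_eq equivalent fully reversed amplitude, MPa (> 0)
#' @param curve an [sn_curve()]
#' @return cycles to failure (vectorized)
#' @export
cycles_to_life <- function(sigma_eq, curve) {
  if (any(sigma_eq <= 0))
    stop_stemopt("equivalent stress must be positive", "domain_error")
  clamp((sigma_eq / curve$a_mpa)^(1 / curve$b), curve$n_min, curve$n_max)
}

#' Binary nodal damage of the cement
#'
#' Per cement node: Goodman-correct the (alternating, mean) pair, look up
#' the S-N life, and mark the node damaged (`d = 1`) when its life is
#' strictly less than the design life (ties count as undamaged, per the
#' strict inequality convention).
#'
#' @param field a `cement_stress_field` (see [solve_implanted()] /
#'   [import_stress_field()])
#' @param curve an [sn_curve()]
#' @param design_life design life, cycles (default 2e6)
#' @param sigma_u cement ultimate strength for the Goodman correction, MPa
#' @return object of class `damage_field`: data.frame with `node_id`,
#'   `sigma_eq_mpa`, `n_cycles`, `d`; attributes `design_life`, `curve`
#' @export
damage_field <- function(field, curve = sn_curve(), design_life = 2e6,
                         sigma_u = builtin_catalog("pmma")$ultimate_mpa) {
  if (!all(c("sigma_a_mpa", "sigma_m_mpa") %in% names(field)))
    stop_stemopt("field must carry sigma_a_mpa and sigma_m_mpa",
                 "invalid_parameter")
  if (nrow(field) < 1L)
    stop_stemopt("cement field must contain at least one node",
                 "invalid_parameter")
  sig_eq <- goodman_correct(field$sigma_a_mpa, field$sigma_m_mpa, sigma_u)
  n <- ifelse(sig_eq > 0, cycles_to_life(pmax(sig_eq, 1e-300), curve),
              curve$n_max)
  out <- data.frame(node_id = field$node_id %||% seq_len(nrow(field)),
                    sigma_eq_mpa = sig_eq, n_cycles = n,
                    d = as.integer(n < design_life))
  attr(out, "design_life") <- design_life
  attr(out, "curve") <- curve
  class(out) <- c("damage_field", "data.frame")
  out
}

#' Critical cement damage accumulation parameter
#'
#' The percentage of cement nodes whose fatigue life is shorter than the
#' design life: `100 * sum(d_i) / i_max`. (The raw damage sum is reported
#' as a percentage of the node count, matching how optimal-design damage
#' values are conventionally tabulated.)
#'
#' @param dmg a [damage_field()]
#' @return damage parameter, percent (in `[0, 100]`)
#' @export
damage_parameter <- function(dmg) {
  if (nrow(dmg) < 1L)
    stop_stemopt("damage field must contain at least one node",
                 "invalid_parameter")
  100 * sum(dmg$d) / nrow(dmg)
}

#' Accumulated damage as a function of loading cycles
#'
#' Evaluates the damage parameter with the design life set to each
#' checkpoint; the history is nondecreasing by construction.
#'
#' @param field a `cement_stress_field`
#' @param curve an [sn_curve()]
#' @param checkpoints increasing cycle counts
#' @param sigma_u cement ultimate strength, MPa
#' @return data.frame with `cycles` and `damage_pct`
#' @export
damage_history <- function(field, curve = sn_curve(),
                           checkpoints = 10^seq(3, 8, by = 0.5),
                           sigma_u = builtin_catalog("pmma")$ultimate_mpa) {
  if (any(diff(checkpoints) <= 0))
    stop_stemopt("checkpoints must be increasing", "invalid_parameter")
  base <- damage_field(field, curve, design_life = checkpoints[1],
                       sigma_u = sigma_u)
  pct <- vapply(checkpoints,
                function(dl) 100 * mean(base$n_cycles < dl), numeric(1))
  data.frame(cycles = checkpoints, damage_pct = pct)
}

#' Export a damage field to CSV
#'
#' @param dmg a [damage_field()]
#' @param path output CSV path
#' @return invisibly, `dmg`
#' @export
export_damage_csv <- function(dmg, path) {
  utils::write.csv(as.data.frame(dmg)[c("node_id", "n_cycles", "d")], path,
                   row.names = FALSE)
  invisible(dmg)
}

#' Read an S-N curve from YAML
#'
#' Expected keys: `a_mpa`, `b`, optional `n_min`, `n_max`.
#'
#' @param path YAML file path
#' @return an [sn_curve()]
#' @export
read_sn_yaml <- function(path) {
  if (!file.exists(path)) stop_stemopt("S-N file not found", "file_error")
  y <- yaml::read_yaml(path)
  sn_curve(a_mpa = y$a_mpa, b = y$b, n_min = y$n_min %||% 1e2,
           n_max = y$n_max %||% 1e8)
}
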