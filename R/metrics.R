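# Stress shielding coefficient and the combined normalized objective.

#' Stress shielding coefficient
#'
#' Compares equivalent alternating stresses at N matched locations on the
#' external bone surface between the intact femur (`sigma_i`) and the
#' implanted femur (`sigma_i'`):
#' \deqn{SSC = \frac{1}{\sigma_{av}} \sqrt{\sum_i (\sigma_i - \sigma_i')^2}}
#' with `sigma_av` the arithmetic mean intact surface stress. The smaller
#' the coefficient, the less stress shielding the implant induces. The
#' root-sum-of-squares residual is the default reading of the typeset
#' formula; `method = "abs"` provides a sum-of-absolute-differences
#' alternative (also divided by `sigma_av`).
#'
#' The coefficient is nonnegative, zero iff the fields are identical, and
#' invariant under a common positive scaling of both fields.
#'
#' @param intact,implanted `stress_samples` data.frames on identical grids
#' @param method `"rss"` (default) or `"abs"`
#' @return dimensionless coefficient
#' @export
stress_shielding_coefficient <- function(intact, implanted,
                                         method = c("rss", "abs")) {
  method <- match.arg(method)
  check_aligned(intact, implanted)
  s_av <- mean(intact$sigma_mpa)
  if (s_av <= 0)
    stop_stemopt("degenerate intact field: mean surface stress is zero",
                 "degenerate_field")
  d <- intact$sigma_mpa - implanted$sigma_mpa
  if (method == "rss") sqrt(sum(d^2)) / s_av else sum(abs(d)) / s_av
}

check_aligned <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      any(abs(a$z_mm - b$z_mm) > 1e-9) ||
      any(abs(a$angle_rad - b$angle_rad) > 1e-9))
    stop_stemopt("stress fields are not on the same sampling locations",
                 "alignment_error")
  invisible(TRUE)
}

#' Running-maximum normalization state for the combined objective
#'
#' Environment carrying the running maxima of the damage parameter and of
#' the stress shielding coefficient over all designs evaluated so far in an
#' optimization run (the dynamic normalization constants of the combined
#' objective). Maxima are nondecreasing over a run.
#'
#' @param max_damage,max_ss optional starting maxima
#' @return an environment of class `objective_state`
#' @export
objective_state <- function(max_damage = 0, max_ss = 0) {
  st <- new.env(parent = emptyenv())
  st$max_damage <- max_damage
  st$max_ss <- max_ss
  st$n_evals <- 0L
  class(st) <- "objective_state"
  st
}

#' Combined normalized objective
#'
#' Sum of squares of the normalized damage parameter and stress shielding
#' coefficient:
#' \deqn{f = (D / D_{max})^2 + (SSC / SSC_{max})^2}
#' where the normalization constants are the running maxima over all
#' designs evaluated so far (updated with the current values before
#' evaluation, so the objective always lies in `[0, 2]`). A term whose
#' running maximum is still zero contributes zero. Because the maxima are
#' dynamic, re-evaluating stored designs after a maximum increases can
#' change their objective values (the evaluation log retains the raw
#' metrics for post-hoc renormalization).
#'
#' @param damage_pct damage parameter, percent (>= 0)
#' @param ss_coef stress shielding coefficient (>= 0)
#' @param state an [objective_state()], updated in place
#' @param update update the running maxima with the current values first?
#' @return objective value (dimensionless)
#' @export
objective_value <- function(damage_pct, ss_coef, state, update = TRUE) {
  if (damage_pct < 0 || ss_coef < 0)
    stop_stemopt("objective inputs must be nonnegative", "domain_error")
  if (update) {
    state$max_damage <- max(state$max_damage, damage_pct)
    state$max_ss <- max(state$max_ss, ss_coef)
    state$n_evals <- state$n_evals + 1L
  }
  td <- if (state$max_damage > 0) (damage_pct / state$max_damage)^2 else 0
  ts <- if (state$max_ss > 0) (ss_coef / state$max_ss)^2 else 0
  td + ts
}

#' Per-station and overall stress reduction of the implanted femur
#'
#' For each axial station, the percent reduction of the mean surface stress
#' relative to the intact femur, `100 * (mean_intact - mean_implanted) /
#' mean_intact`; `overall` aggregates the same ratio over all requested
#' locations (the implanted span when the implanted field carries an
#' `in_span` flag, every location otherwise).
#'
#' @param intact,implanted aligned `stress_samples` data.frames
#' @param span_only restrict `overall` to the implanted span (needs the
#'   `in_span` column produced by [solve_implanted()])
#' @return list with `per_station` (data.frame: `axial`, `z_mm`,
#'   `reduction_pct`) and `overall` (percent)
#' @export
stress_reduction_profile <- function(intact, implanted, span_only = TRUE) {
  check_aligned(intact, implanted)
  mi <- tapply(intact$sigma_mpa, intact$axial, mean)
  mp <- tapply(implanted$sigma_mpa, implanted$axial, mean)
  zz <- tapply(intact$z_mm, intact$axial, mean)
  per <- data.frame(axial = as.integer(names(mi)), z_mm = as.numeric(zz),
                    reduction_pct = 100 * (mi - mp) / mi)
  sel <- if (span_only && !is.null(implanted$in_span)) implanted$in_span
         else rep(TRUE, nrow(intact))
  overall <- 100 * (mean(intact$sigma_mpa[sel]) -
                    mean(implanted$sigma_mpa[sel])) /
    mean(intact$sigma_mpa[sel])
  list(per_station = per, overall = overall)
}
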