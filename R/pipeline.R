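# Full single-design evaluation pipeline (geometry -> surrogate solve ->
# fatigue -> metrics) and the run_* entry points behind the command-line
# wrapper.

#' Default run configuration
#'
#' Bundles the documented defaults of every module: skeleton, design
#' bounds, canal profile, surrogate femur, walking load case, materials,
#' S-N curve, design life, sampling grid and optimizer settings.
#'
#' @param stem_material `"ti6al4v"`, `"fgm"`, a [material()] or an
#'   [fgm_layout()]
#' @param n_axial,n_circ surface sampling grid (defaults 95 x 32 = 3040
#'   locations)
#' @param seed RNG seed for the optimizer
#' @return a named list of class `run_config`
#' @export
default_config <- function(stem_material = "ti6al4v", n_axial = 95,
                           n_circ = 32, seed = 1) {
  sm <- if (inherits(stem_material, c("material", "fgm_layout")))
    stem_material
  else if (identical(stem_material, "fgm")) fgm_layout()
  else builtin_catalog(stem_material)
  cfg <- list(
    skeleton = stem_skeleton(),
    bounds = design_bounds(),
    canal = canal_profile(),
    femur = surrogate_femur(),
    loads = load_case(),
    stem_material = sm,
    cement = builtin_catalog("pmma"),
    sn = sn_curve(),
    design_life = 2e6,
    n_axial = n_axial, n_circ = n_circ,
    optimizer = list(n_init = 10, max_restarts = 30, offset = 0.2,
                     weighting = "variance"),
    seed = seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' Any subset of the configurable scalars may appear; missing entries fall
#' back to [default_config()]. Recognized keys: `stem_material`
#' ("ti6al4v"/"fgm"), `n_axial`, `n_circ`, `seed`, `design_life`,
#' `sn: {a_mpa, b, n_min, n_max}`, `loads: {joint_kn, joint_angle_deg,
#' abductor_kn, abductor_angle_deg, joint_offset_mm, abductor_offset_mm}`,
#' `femur: {length, z_stations, outer_r, canal_r}`, `optimizer: {n_init,
#' max_restarts, offset, weighting}`.
#'
#' @param path YAML file path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_stemopt("config file not found", "file_error")
  y <- yaml::read_yaml(path)
  cfg <- default_config(stem_material = y$stem_material %||% "ti6al4v",
                        n_axial = y$n_axial %||% 95,
                        n_circ = y$n_circ %||% 32,
                        seed = y$seed %||% 1)
  if (!is.null(y$design_life)) cfg$design_life <- y$design_life
  if (!is.null(y$sn))
    cfg$sn <- sn_curve(y$sn$a_mpa %||% 90, y$sn$b %||% -0.13,
                       y$sn$n_min %||% 1e2, y$sn$n_max %||% 1e8)
  if (!is.null(y$loads))
    cfg$loads <- do.call(load_case, y$loads)
  if (!is.null(y$femur))
    cfg$femur <- surrogate_femur(
      length = y$femur$length %||% 400,
      z_stations = as.numeric(y$femur$z_stations),
      outer_r = as.numeric(y$femur$outer_r),
      canal_r = as.numeric(y$femur$canal_r))
  if (!is.null(y$optimizer))
    cfg$optimizer <- utils::modifyList(cfg$optimizer, y$optimizer)
  cfg
}

#' Evaluate one stem design end to end
#'
#' Runs the full chain for a single design vector: admissibility check,
#' intact and implanted surrogate solves, cement fatigue damage, stress
#' shielding coefficient. An inadmissible design short-circuits with the
#' constraint report.
#'
#' @param values 20-value design vector (or a [design_vector()])
#' @param config a `run_config` (see [default_config()])
#' @param intact optional precomputed intact `stress_samples` (reused
#'   across designs during optimization)
#' @return list: `admissible`, `report` (constraint report), and for
#'   admissible designs `damage_pct`, `ss_coef`, `reduction`, `bone`,
#'   `cement`, `damage`
#' @export
evaluate_design <- function(values, config = default_config(),
                            intact = NULL) {
  dv <- if (inherits(values, "design_vector")) values else
    design_vector(values, config$bounds)
  report <- check_constraints(dv, config$canal, skeleton = config$skeleton)
  if (!report$admissible)
    return(list(admissible = FALSE, report = report))
  if (is.null(intact))
    intact <- solve_intact(config$femur, config$loads,
                           config$n_axial, config$n_circ)
  assembly <- implant_assembly(dv, config$femur, config$stem_material,
                               config$cement, config$skeleton)
  sol <- solve_implanted(assembly, config$loads,
                         config$n_axial, config$n_circ)
  dmg <- damage_field(sol$cement, config$sn, config$design_life,
                      sigma_u = config$cement$ultimate_mpa)
  list(admissible = TRUE, report = report,
       damage_pct = damage_parameter(dmg),
       ss_coef = stress_shielding_coefficient(intact, sol$bone),
       reduction = stress_reduction_profile(intact, sol$bone),
       bone = sol$bone, cement = sol$cement, damage = dmg)
}

#' Objective evaluator for the stem design problem
#'
#' Wraps [evaluate_design()] into the scalar objective consumed by
#' [taguchi_optimize()], sharing one [objective_state()] (running
#' normalization maxima) and one precomputed intact solution across all
#' evaluations. Inadmissible designs receive the penalized objective
#' `2 + violation magnitude` so orthogonal arrays stay complete. The
#' closure appends one JSONL record per design to `log_path` when given.
#'
#' @param config a `run_config`
#' @param state an [objective_state()] (created if missing)
#' @param log_path optional JSONL evaluation-log path
#' @return function(values) -> objective, with attributes `state` and
#'   `intact`
#' @export
design_evaluator <- function(config = default_config(),
                             state = objective_state(), log_path = NULL) {
  intact <- solve_intact(config$femur, config$loads,
                         config$n_axial, config$n_circ)
  chash <- config_hash(config[c("n_axial", "n_circ", "design_life", "seed")])
  f <- function(values) {
    res <- evaluate_design(values, config, intact = intact)
    if (!res$admissible) {
      obj <- 2 + res$report$violation_magnitude
      rec <- list(design = values, admissible = FALSE,
                  violations = res$report$violations, objective = obj,
                  config_hash = chash)
    } else {
      obj <- objective_value(res$damage_pct, res$ss_coef, state)
      rec <- list(design = values, admissible = TRUE,
                  damage_pct = res$damage_pct, ss_coef = res$ss_coef,
                  objective = obj,
                  max_damage = state$max_damage, max_ss = state$max_ss,
                  config_hash = chash)
    }
    if (!is.null(log_path))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          sep = "", file = log_path, append = TRUE)
    obj
  }
  attr(f, "state") <- state
  attr(f, "intact") <- intact
  f
}

# ---------------------------------------------------------------------------
# command entry points (the Rscript wrapper in inst/cli dispatches to these)

read_design_values <- function(path, bounds) {
  if (!file.exists(path)) stop_stemopt("design-vector file not found",
                                       "file_error")
  v <- if (grepl("\\.ya?ml$", path)) as.numeric(unlist(yaml::read_yaml(path)))
       else as.numeric(utils::read.csv(path, header = FALSE)[[1]])
  v
}

#' Build and export one stem design
#'
#' Validates the design, writes the STL mesh and the station-profile CSV,
#' and returns the constraint report. With `slices` set, additionally
#' writes the lengthwise layer boundaries (e.g. 11 slices for the layered
#' functionally graded stem).
#'
#' @param values 20-value design vector (or a path readable by the CLI)
#' @param config a `run_config`
#' @param out_dir output directory
#' @param slices optional number of lengthwise slices to export boundaries
#'   for
#' @return list: `report`, `stl`, `profiles`, optional `slices_csv`
#' @export
run_build <- function(values, config = default_config(),
                      out_dir = ".", slices = NULL) {
  if (is.character(values)) values <- read_design_values(values)
  dv <- design_vector(values, config$bounds)
  report <- check_constraints(dv, config$canal, skeleton = config$skeleton)
  stem <- build_stem(dv, config$skeleton)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stl <- file.path(out_dir, "stem.stl")
  prof <- file.path(out_dir, "profiles.csv")
  export_stl(stem, stl)
  export_profiles_csv(stem, prof)
  out <- list(report = report, stl = stl, profiles = prof)
  if (!is.null(slices)) {
    sc <- file.path(out_dir, "slices.csv")
    bz <- seq(0, config$skeleton$total_length, length.out = slices + 1L)
    utils::write.csv(data.frame(layer = seq_len(slices),
                                z_from_tip_lo = bz[-length(bz)],
                                z_from_tip_hi = bz[-1]),
                     sc, row.names = FALSE)
    out$slices_csv <- sc
  }
  out
}

#' Evaluate one stem design and report its metrics
#'
#' @param values 20-value design vector
#' @param config a `run_config`
#' @param out optional JSON output path
#' @return the [evaluate_design()] result, with `config_hash` attached
#' @export
run_evaluate <- function(values, config = default_config(), out = NULL) {
  if (is.character(values)) values <- read_design_values(values)
  res <- evaluate_design(values, config)
  res$config_hash <- config_hash(config[c("n_axial", "n_circ",
                                          "design_life", "seed")])
  if (!is.null(out)) {
    rec <- list(admissible = res$admissible,
                violations = res$report$violations,
                config_hash = res$config_hash)
    if (res$admissible) {
      rec$damage_pct <- res$damage_pct
      rec$ss_coef <- res$ss_coef
      rec$mean_reduction_pct <- res$reduction$overall
    }
    jsonlite::write_json(rec, out, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Optimize the stem design
#'
#' Runs the Taguchi orthogonal-array optimizer on the full evaluation
#' pipeline with the configured restart budget and writes the ranked
#' optima table plus the JSONL evaluation log.
#'
#' @param config a `run_config`
#' @param out_dir output directory (optima.csv, evaluations.jsonl)
#' @return the [taguchi_optimize()] result with the shared
#'   [objective_state()] attached as `state`
#' @export
run_optimize <- function(config = default_config(), out_dir = NULL) {
  state <- objective_state()
  log_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    lp <- file.path(out_dir, "evaluations.jsonl")
    if (file.exists(lp)) file.remove(lp)
    header <- list(n_init = config$optimizer$n_init,
                   max_restarts = config$optimizer$max_restarts,
                   seed = config$seed,
                   config_hash = config_hash(config[c("n_axial", "n_circ",
                                                      "design_life",
                                                      "seed")]))
    cat(jsonlite::toJSON(header, auto_unbox = TRUE), "\n", sep = "",
        file = lp)
    lp
  } else NULL
  ev <- design_evaluator(config, state, log_path)
  res <- taguchi_optimize(
    ev, lower = config$bounds$lower, upper = config$bounds$upper,
    integer = config$bounds$integer,
    n_init = config$optimizer$n_init,
    max_restarts = config$optimizer$max_restarts,
    seed = config$seed, offset = config$optimizer$offset,
    weighting = config$optimizer$weighting)
  res$state <- state
  if (!is.null(out_dir))
    utils::write.csv(res$optima, file.path(out_dir, "optima.csv"),
                     row.names = FALSE)
  res
}
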