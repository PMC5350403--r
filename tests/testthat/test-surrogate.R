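# Composite-beam surrogate solver: closed-form limits, composite-section
# oracle, equilibrium closure, stress-field exchange.

zero_loads <- load_case(joint_kn = 0, abductor_kn = 0)

test_that("femur geometry validation", {
  expect_error(surrogate_femur(canal_r = c(13, 9, 9, 10.5, 12.5)),
               class = "invalid_parameter")
  expect_error(surrogate_femur(z_stations = c(0, 0, 300, 350, 400)),
               class = "invalid_parameter")
})

test_that("zero loads produce an all-zero surface field", {
  s <- solve_intact(tube_femur(), zero_loads, 10, 8)
  expect_equal(s$sigma_mpa, rep(0, 80))
})

test_that("pure axial load on a uniform tube gives sigma = F / A everywhere", {
  lc <- load_case(joint_kn = 2.5, joint_angle_deg = 0, joint_offset_mm = 0,
                  abductor_kn = 0)
  fem <- tube_femur(outer = 12.5, canal = 9)
  s <- solve_intact(fem, lc, 12, 8)
  A <- pi * (12.5^2 - 9^2)
  expect_equal(s$sigma_mpa, rep(2500 / A / 2, nrow(s)), tolerance = 1e-12)
})

test_that("transverse tip load reproduces the cantilever bending closed form", {
  # purely transverse force at the free end: M(z) = F (L - z)
  lc <- load_case(joint_kn = 2, joint_angle_deg = 90, joint_offset_mm = 0,
                  abductor_kn = 0)
  fem <- tube_femur(outer = 12.5, canal = 9, length = 400)
  s <- solve_intact(fem, lc, 10, 16)
  I <- pi / 4 * (12.5^4 - 9^4)
  expected <- abs(-2000 * (400 - s$z_mm) / I * 12.5 * cos(s$angle_rad)) / 2
  expect_equal(s$sigma_mpa, expected, tolerance = 1e-10)
})

test_that("all-bone assembly matches the solid intact femur (homogeneous limit)", {
  cfg <- default_config()
  bone <- builtin_catalog("bone")
  fem <- cfg$femur
  fem_solid <- surrogate_femur(length = fem$length,
                               z_stations = fem$z_stations,
                               outer_r = fem$outer_r,
                               canal_r = rep(0, length(fem$canal_r)))
  asm <- implant_assembly(mid_design(), fem, stem_material = bone,
                          cement = bone)
  sol <- solve_implanted(asm, cfg$loads, 40, 16)
  int_solid <- solve_intact(fem_solid, cfg$loads, 40, 16)
  int_hollow <- solve_intact(fem, cfg$loads, 40, 16)
  sp <- sol$bone$in_span
  scale <- max(int_solid$sigma_mpa)
  expect_lt(max(abs(sol$bone$sigma_mpa[sp] - int_solid$sigma_mpa[sp])) /
              scale, 1e-8)
  # outside the span the implanted femur is the plain cortical tube
  expect_lt(max(abs(sol$bone$sigma_mpa[!sp] - int_hollow$sigma_mpa[!sp])) /
              scale, 1e-12)
})

test_that("concentric circular composite section matches the transformed-section closed form", {
  fem <- tube_femur(outer = 12.5, canal = 9, length = 400)
  lc <- load_case()
  asm <- implant_assembly(circular_design(6.5), fem,
                          skeleton = straight_skeleton(distal_radius = 6.5))
  n_ax <- 40; n_circ <- 8
  sol <- solve_implanted(asm, lc, n_ax, n_circ)
  sp <- which(sol$bone$in_span)
  z <- sol$bone$z_mm[sp]
  sf <- stemopt:::section_forces(lc, 400, z)
  Eb <- 18600; Ec <- 2280; Es <- 110000
  At <- pi * (12.5^2 - 9^2); It <- pi / 4 * (12.5^4 - 9^4)
  As <- pi * 6.5^2;          Is <- pi / 4 * 6.5^4
  Ac <- pi * 9^2 - As;       Ic <- pi / 4 * 9^4 - Is
  EA <- Eb * At + Ec * Ac + Es * As
  EI <- Eb * It + Ec * Ic + Es * Is
  expected <- abs(Eb * (sf$N / EA +
                        sf$M / EI * 12.5 * cos(sol$bone$angle_rad[sp]))) / 2
  expect_equal(sol$bone$sigma_mpa[sp], expected, tolerance = 1e-8)
  # cement node stress at mid-thickness follows the same strain state
  k <- which.max(sol$cement$sigma_a_mpa)
  r_mid <- (6.5 + 9) / 2
  sfk <- stemopt:::section_forces(lc, 400, sol$cement$z_mm[k])
  exp_c <- abs(Ec * (sfk$N / EA + sfk$M / EI * r_mid *
                     cos(sol$cement$angle_rad[k]))) / 2
  expect_equal(sol$cement$sigma_a_mpa[k], exp_c, tolerance = 1e-6)
})

test_that("section stress resultants integrate back to the applied forces", {
  cfg <- default_config()
  asm <- implant_assembly(mid_design(), cfg$femur)
  # reconstruct (eps0, kappa) at a key cross-section height and integrate
  # sigma = E (eps0 + kappa y) with independent section integrals
  z <- 351.75                          # station 3 sits exactly here
  sf <- stemopt:::section_forces(cfg$loads, 400, z)
  ro <- stemopt:::femur_outer_r(cfg$femur, z)
  rc <- stemopt:::femur_canal_r(cfg$femur, z)
  stem_pr <- section_properties(mid_design()$sections$station3, n = 8192)
  Eb <- 18600; Ec <- 2280; Es <- 110000
  EA <- Eb * pi * (ro^2 - rc^2) + Ec * (pi * rc^2 - stem_pr$area) +
    Es * stem_pr$area
  EI <- Eb * pi / 4 * (ro^4 - rc^4) +
    Ec * (pi / 4 * rc^4 - stem_pr$Ix) + Es * stem_pr$Ix
  eps0 <- sf$N / EA
  kap <- sf$M / EI
  # resultants: N = sum E (eps0 A + kappa S_y), S_y = 0 by symmetry;
  # M = sum E (eps0 S_y + kappa I) -- S_y independently via polygon centroid
  th <- seq(0, 2 * pi, length.out = 4097)[-4097]
  pts <- profile_point(mid_design()$sections$station3, th)
  Sy_stem <- stem_pr$area * stem_pr$centroid["y"]
  N_num <- Eb * eps0 * pi * (ro^2 - rc^2) +
    Ec * (eps0 * (pi * rc^2 - stem_pr$area) - kap * Sy_stem) +
    Es * (eps0 * stem_pr$area + kap * Sy_stem)
  M_num <- kap * EI
  expect_equal(unname(N_num), sf$N, tolerance = 1e-6)
  expect_equal(M_num, sf$M, tolerance = 1e-6)
  expect_lt(abs(Sy_stem) / stem_pr$area, 1e-9)  # section symmetric in y
})

test_that("stiffer implants never raise bone-surface stress in the span", {
  cfg <- default_config()
  moduli <- c(20, 50, 110, 200)
  fields <- lapply(moduli, function(E) {
    asm <- implant_assembly(mid_design(), cfg$femur,
                            stem_material = material("m", E))
    solve_implanted(asm, cfg$loads, 30, 8)$bone
  })
  for (i in seq_len(length(moduli) - 1)) {
    expect_true(all(fields[[i + 1]]$sigma_mpa <=
                    fields[[i]]$sigma_mpa + 1e-9))
  }
})

test_that("graded stems shield less than the uniform titanium stem", {
  cfg <- default_config()
  intact <- solve_intact(cfg$femur, cfg$loads, 40, 16)
  asm_ti <- implant_assembly(mid_design(), cfg$femur)
  asm_fgm <- implant_assembly(mid_design(), cfg$femur,
                              stem_material = fgm_layout())
  ss_ti <- stress_shielding_coefficient(
    intact, solve_implanted(asm_ti, cfg$loads, 40, 16)$bone)
  ss_fgm <- stress_shielding_coefficient(
    intact, solve_implanted(asm_fgm, cfg$loads, 40, 16)$bone)
  expect_lt(ss_fgm, ss_ti)
})

test_that("stress fields round-trip through CSV; bad files are diagnosed", {
  cfg <- default_config()
  intact <- solve_intact(cfg$femur, cfg$loads, 10, 8)
  p <- withr::local_tempfile(fileext = ".csv")
  export_stress_field(intact, p)
  back <- import_stress_field(p, "surface")
  expect_equal(back$sigma_mpa, intact$sigma_mpa)
  expect_equal(attr(back, "n_axial"), 10)

  # negative stress -> validation error naming the row
  df <- utils::read.csv(p)
  df$sigma_mpa[3] <- -1
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(import_stress_field(p, "surface"),
               class = "validation_error")

  # missing column -> parse error naming it
  df$sigma_mpa <- NULL
  utils::write.csv(df, p, row.names = FALSE)
  err <- tryCatch(import_stress_field(p, "surface"),
                  parse_error = function(e) conditionMessage(e))
  expect_match(err, "sigma_mpa")

  # cement field round trip
  cem <- make_cement_field(50, seed = 4)
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_stress_field(cem, p2)
  back2 <- import_stress_field(p2, "cement")
  expect_equal(back2$sigma_a_mpa, cem$sigma_a_mpa)
})
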