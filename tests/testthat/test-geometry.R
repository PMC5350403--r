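# Parametric cross sections, section properties, loft, cement mantle and
# admissibility constraints.

test_that("profile curve is closed, continuous at the half junction, and hits the circle case", {
  cs <- cross_section(6, 6, 6, 2)
  th <- seq(0, 2 * pi, length.out = 97)
  r <- sqrt(rowSums(profile_point(cs, th)^2))
  expect_equal(r, rep(6, length(th)), tolerance = 1e-12)

  csa <- cross_section(10, 7, 5, 3)
  expect_lt(max(abs(profile_point(csa, 0) - profile_point(csa, 2 * pi))),
            1e-9)
  # continuity where the a1 half hands over to the a2 half (x = 0)
  lhs <- profile_point(csa, pi / 2 - 1e-12)
  rhs <- profile_point(csa, pi / 2 + 1e-12)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("invalid cross-section parameters are rejected", {
  expect_error(cross_section(-1, 6, 6, 2), class = "invalid_parameter")
  expect_error(cross_section(6, 6, 0, 2), class = "invalid_parameter")
  expect_error(cross_section(6, 6, 6, 1), class = "invalid_parameter")
  expect_error(cross_section(6, 6, 6, 2.5), class = "invalid_parameter")
})

test_that("section areas match closed forms: circle, two half-ellipses, gamma-function superellipse", {
  p <- section_properties(cross_section(10, 10, 8, 2))
  expect_equal(p$area, pi * 10 * 8, tolerance = 1e-5)

  p2 <- section_properties(cross_section(12, 8, 8, 2))
  expect_equal(p2$area, 80 * pi, tolerance = 1e-5)
  # composite centroid of the two half-ellipses: 16 / (3 pi)
  expect_equal(unname(p2$centroid["x"]), 16 / (3 * pi), tolerance = 1e-5)
  expect_equal(unname(p2$centroid["y"]), 0, tolerance = 1e-9)

  # gamma closed form 4 a b G(1+1/p)^2 / G(1+2/p), frozen value for p = 4
  p4 <- section_properties(cross_section(1, 1, 1, 4))
  expect_equal(p4$area, 3.708149, tolerance = 1e-4)
  expect_equal(p4$area, superellipse_area(1, 1, 4), tolerance = 1e-4)

  # near-square limit at large exponent
  p9 <- section_properties(cross_section(5, 5, 5, 9))
  expect_equal(p9$area, superellipse_area(5, 5, 9), tolerance = 1e-4)
  expect_lt(abs(p9$area - 100) / 100, 0.02)
})

test_that("circle second moments match pi r^4 / 4", {
  pr <- section_properties(cross_section(6, 6, 6, 2))
  expect_equal(pr$Ix, pi / 4 * 6^4, tolerance = 1e-5)
  expect_equal(pr$Iy, pi / 4 * 6^4, tolerance = 1e-5)
})

test_that("area is monotone nondecreasing in each semiaxis and in p", {
  base <- c(a1 = 6, a2 = 7, b = 5, p = 3)
  area_of <- function(v)
    section_properties(cross_section(v[["a1"]], v[["a2"]], v[["b"]],
                                     v[["p"]]))$area
  for (var in names(base)) {
    grid <- if (var == "p") 2:6 else seq(4, 9, by = 1)
    areas <- vapply(grid, function(g) {
      v <- base; v[[var]] <- g; area_of(v)
    }, numeric(1))
    expect_true(all(diff(areas) > -1e-9), info = var)
  }
})

test_that("design vector validates length, bounds and integer exponents", {
  b <- design_bounds()
  expect_equal(nrow(b), 20L)
  dv <- mid_design(b)
  expect_length(dv$values, 20L)
  expect_error(design_vector(rep(1, 19), b), class = "constraint_error")
  bad <- dv$values; bad[1] <- b$upper[1] + 1
  expect_error(design_vector(bad, b), class = "constraint_error")
  frac <- dv$values; frac[4] <- 2.5    # station-2 exponent
  expect_error(design_vector(frac, b), class = "constraint_error")
})

test_that("stems build at both bound extremes and deterministically", {
  b <- design_bounds()
  lo <- design_vector(ifelse(b$integer, b$lower, b$lower), b)
  hi <- design_vector(b$upper, b)
  s_lo <- sample_surface(build_stem(lo), 20, 16)
  s_hi <- sample_surface(build_stem(hi), 20, 16)
  expect_true(all(is.finite(s_lo$points)))
  expect_true(all(is.finite(s_hi$points)))
  # volumes enclose properly at both extremes
  expect_gt(mesh_volume(stemopt:::triangulate_loft(s_lo$points)), 0)
  expect_gt(mesh_volume(stemopt:::triangulate_loft(s_hi$points)), 0)

  again <- sample_surface(build_stem(design_vector(b$upper, b)), 20, 16)
  expect_identical(s_hi$points, again$points)
})

test_that("degenerate cylinder stem samples at constant radius and its STL volume matches pi r^2 L", {
  stem <- build_stem(circular_design(6), straight_skeleton())
  surf <- sample_surface(stem, 80, 64)
  r <- sqrt(surf$points[, , 1]^2 + surf$points[, , 2]^2)
  expect_equal(max(abs(r - 6)), 0, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".stl")
  export_stl(stem, path, n_u = 80, n_v = 64)
  tri <- read_stl_ascii(path)
  v_analytic <- pi * 36 * 185
  expect_lt(abs(mesh_volume(tri) - v_analytic) / v_analytic, 0.01)
})

test_that("minimal 4 x 4 sampling still yields a valid closed mesh", {
  stem <- build_stem(mid_design())
  surf <- sample_surface(stem, 4, 4)
  tri <- stemopt:::triangulate_loft(surf$points)
  expect_gt(mesh_volume(tri), 0)
  expect_error(sample_surface(stem, 3, 8), class = "invalid_parameter")
})

test_that("STL export round-trips through the ASCII reader", {
  stem <- build_stem(mid_design())
  path <- withr::local_tempfile(fileext = ".stl")
  tri <- export_stl(stem, path, n_u = 24, n_v = 16)
  tri2 <- read_stl_ascii(path)
  expect_equal(dim(tri2), dim(tri))
  expect_equal(mesh_volume(tri2), mesh_volume(tri), tolerance = 1e-6)
})

test_that("profile CSV export covers all stations", {
  stem <- build_stem(mid_design())
  path <- withr::local_tempfile(fileext = ".csv")
  df <- export_profiles_csv(stem, path, n_v = 16)
  expect_true(file.exists(path))
  expect_equal(sort(unique(df$station_id)), 1:6)
  expect_equal(nrow(df), 6 * 16)
})

test_that("concentric circular stem in circular canal gives uniform mantle thickness", {
  stem <- build_stem(circular_design(6), straight_skeleton())
  rings <- cement_sections(stem, uniform_canal(8.5))
  for (rg in rings) {
    expect_equal(rg$min, 2.5, tolerance = 1e-9)
    expect_equal(rg$max, 2.5, tolerance = 1e-9)
  }
})

test_that("elliptical stem in circular canal is thinnest at the long axis", {
  b <- design_bounds()
  v <- mid_design(b)$values
  v[1:3] <- c(6, 6, 7)                 # station 2: a1 = a2 = 6, b = 7
  stem <- build_stem(design_vector(v, b))
  canal <- lapply(c(8.5, 9.5, 10.5, 12.5),
                  function(r) cross_section(r, r, r, 2))
  rg <- cement_sections(stem, canal, n_angle = 1440)[[2]]
  expect_equal(rg$min, 2.5, tolerance = 1e-6)
  # minimum sits on the b (medial-lateral) axis
  at_min <- rg$angle[which.min(rg$thickness)]
  expect_lt(min(abs(at_min - c(pi / 2, 3 * pi / 2))), 0.02)
})

test_that("a stem touching the canal raises a geometry violation", {
  stem <- build_stem(circular_design(6), straight_skeleton())
  expect_error(cement_sections(stem, uniform_canal(6)),
               class = "geometry_violation")
})

test_that("constraint checker accepts the mid-bounds design and flags thin/thick mantles", {
  rep_ok <- check_constraints(mid_design())
  expect_true(rep_ok$admissible)
  expect_length(rep_ok$violations, 0L)
  expect_equal(rep_ok$min_cement_thickness, 2.5, tolerance = 1e-6)

  # narrow the canal at station 3 only: mantle falls to 1.2 mm there
  canal_thin <- lapply(c(8.5, 9, 9.2, 12.5),
                       function(r) cross_section(r, r, r, 2))
  thin <- check_constraints(mid_design(), canal_thin)
  expect_false(thin$admissible)
  expect_true("cement_too_thin" %in% thin$violations)
  expect_equal(thin$min_cement_thickness, 1.2, tolerance = 1e-6)

  # widen the canal at station 4 only: mantle grows to ~3.6 mm there
  canal_thick <- lapply(c(8.5, 9, 10.5, 13.6),
                        function(r) cross_section(r, r, r, 2))
  thick <- check_constraints(mid_design(), canal_thick)
  expect_false(thick$admissible)
  expect_true("cement_too_thick" %in% thick$violations)

  # a stem crossing the canal boundary is reported, not crashed on
  canal_cross <- lapply(c(8.5, 9, 7.5, 12.5),
                        function(r) cross_section(r, r, r, 2))
  crossed <- check_constraints(mid_design(), canal_cross)
  expect_false(crossed$admissible)
  expect_true("stem_outside_canal" %in% crossed$violations)
})

test_that("constraint report is invariant under rigid rotation of stem and canal together", {
  stem <- build_stem(mid_design())
  r0 <- cement_sections(stem, canal_profile(), n_angle = 1440, rotation = 0)
  r1 <- cement_sections(stem, canal_profile(), n_angle = 1440,
                        rotation = 0.7)
  for (s in seq_along(r0)) {
    expect_equal(r1[[s]]$min, r0[[s]]$min, tolerance = 1e-4)
    expect_equal(r1[[s]]$max, r0[[s]]$max, tolerance = 1e-4)
  }
})

test_that("distal-bulge designs violate the taper rule", {
  # the default bounds exclude bulges by construction, so widen them:
  # a fat station 2 above a slim station 3 is not insertable
  b <- design_bounds()
  b$lower[b$station %in% 2:3 & !b$integer] <- 6
  b$upper[b$station %in% 2:3 & !b$integer] <- 9
  v <- mid_design(b)$values
  v[1:3] <- 9       # station 2 semiaxes
  v[5:7] <- 6       # station 3 semiaxes
  rep_ <- check_constraints(design_vector(v, b))
  expect_false(rep_$admissible)
  expect_true("distal_bulge" %in% rep_$violations)
  # the rule can be switched off
  rep_off <- check_constraints(design_vector(v, b), taper_rule = FALSE)
  expect_false("distal_bulge" %in% rep_off$violations)
})
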