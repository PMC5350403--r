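# Shared test helpers: custom bounds/designs that produce analytically
# tractable geometry (circular sections, straight skeletons).

# bounds table allowing the same circular section at every variable station
uniform_bounds <- function(radius = 6.5, p = 2) {
  b <- design_bounds()
  b$lower <- ifelse(b$integer, p, radius)
  b$upper <- ifelse(b$integer, p, radius)
  b
}

# a design vector whose five variable sections are identical circles
circular_design <- function(radius = 6.5, p = 2) {
  b <- uniform_bounds(radius, p)
  design_vector(rep(c(radius, radius, radius, p), 5), b)
}

# straight skeleton (neck collinear with the prosthesis axis): the lofted
# stem of a circular_design with radius = distal_radius is then an exact
# circular cylinder
straight_skeleton <- function(total_length = 185, axis_length = 150,
                              distal_radius = 6)
  stem_skeleton(total_length = total_length, axis_length = axis_length,
                neck_angle_deg = 180, distal_radius = distal_radius)

# constant-section femur tube
tube_femur <- function(outer = 12.5, canal = 9, length = 400)
  surrogate_femur(length = length, z_stations = c(0, length),
                  outer_r = c(outer, outer), canal_r = c(canal, canal))

# canal profile with a single radius at all four in-bone stations
uniform_canal <- function(radius)
  lapply(rep(radius, 4), function(r) cross_section(r, r, r, 2))
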