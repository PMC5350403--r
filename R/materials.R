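# Material catalogs: homogeneous metals, bone, PMMA cement, and layered
# functionally graded stems.

#' Define a linear-elastic material
#'
#' @param name material label
#' @param modulus_gpa elastic modulus, GPa (> 0)
#' @param poisson Poisson's ratio (0, 0.5); 0.3 throughout the built-in
#'   catalog
#' @param ultimate_mpa ultimate strength, MPa (used for the Goodman
#'   correction; only meaningful for the cement)
#' @return object of class `material`
#' @export
material <- function(name, modulus_gpa, poisson = 0.3, ultimate_mpa = NA) {
  if (!is_number(modulus_gpa) || modulus_gpa <= 0)
    stop_stemopt("modulus must be a positive number", "invalid_parameter")
  if (!is_number(poisson) || poisson <= 0 || poisson >= 0.5)
    stop_stemopt("Poisson ratio must lie in (0, 0.5)", "invalid_parameter")
  structure(list(name = name, modulus_gpa = modulus_gpa, poisson = poisson,
                 ultimate_mpa = ultimate_mpa), class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("material %s: E = %.4g GPa, nu = %.2f\n",
              x$name, x$modulus_gpa, x$poisson))
  invisible(x)
}

#' Built-in material catalog
#'
#' Cortical bone (18.6 GPa), PMMA bone cement (2.28 GPa, ultimate strength
#' 70 MPa for the Goodman correction) and Ti-6Al-4V titanium alloy
#' (110 GPa); Poisson's ratio 0.3 for all.
#'
#' @param name optional material name (`"bone"`, `"pmma"`, `"ti6al4v"`); if
#'   omitted the whole catalog is returned
#' @return a [material()] or a named list of them
#' @export
builtin_catalog <- function(name = NULL) {
  cat_ <- list(
    bone = material("bone", 18.6),
    pmma = material("pmma", 2.28, ultimate_mpa = 70),
    ti6al4v = material("ti6al4v", 110))
  if (is.null(name)) return(cat_)
  if (!name %in% names(cat_))
    stop_stemopt(sprintf("unknown material '%s' (have: %s)", name,
                         paste(names(cat_), collapse = ", ")),
                 "lookup_error")
  cat_[[name]]
}

#' Functionally graded stem layout
#'
#' Lengthwise slicing of the stem into layers with piecewise-constant
#' modulus. Layer 1 is the most proximal layer; the default schedule is
#' eleven equal-length layers with moduli 120, 110, 90, 80, 70, 60, 50, 40,
#' 30, 20, 10 GPa from proximal to distal. `layer1_gpa` switches the first
#' layer to another value (e.g. 110 to match Ti-6Al-4V exactly).
#'
#' @param moduli_gpa per-layer modulus, proximal first
#' @param length total stem length the layers span, mm
#' @param boundaries optional strictly increasing layer boundaries
#'   (length(moduli) + 1 values spanning `[0, length]`, measured from the
#'   distal tip); equal-length layers by default
#' @param layer1_gpa optional override of the proximal layer modulus
#' @return object of class `fgm_layout`
#' @export
fgm_layout <- function(moduli_gpa = c(120, 110, 90, 80, 70, 60, 50, 40,
                                      30, 20, 10),
                       length = 185, boundaries = NULL, layer1_gpa = NULL) {
  if (!is.null(layer1_gpa)) moduli_gpa[1] <- layer1_gpa
  n <- base::length(moduli_gpa)
  if (is.null(boundaries))
    boundaries <- seq(0, length, length.out = n + 1L)
  if (base::length(boundaries) != n + 1L || any(diff(boundaries) <= 0) ||
      abs(boundaries[1]) > 1e-9 || abs(boundaries[n + 1L] - length) > 1e-9)
    stop_stemopt("boundaries must be strictly increasing and span [0, length]",
                 "invalid_parameter")
  if (any(moduli_gpa <= 0))
    stop_stemopt("layer moduli must be positive", "invalid_parameter")
  structure(list(n_layers = n, moduli_gpa = moduli_gpa,
                 boundaries = boundaries, length = length),
            class = "fgm_layout")
}

#' @export
print.fgm_layout <- function(x, ...) {
  cat(sprintf("fgm_layout: %d layers over %.0f mm, E = %s GPa (proximal first)\n",
              x$n_layers, x$length, paste(x$moduli_gpa, collapse = " ")))
  invisible(x)
}

#' Modulus of a functionally graded stem at a lengthwise position
#'
#' Piecewise-constant lookup. `z` is measured from the distal tip; layer 1
#' is proximal, so small `z` falls in the last (softest) layer. Points on a
#' layer boundary belong to the more-proximal layer.
#'
#' @param layout an [fgm_layout()]
#' @param z position(s) along the stem, mm, in `[0, length]`
#' @return modulus, GPa (vectorized over `z`)
#' @export
modulus_at <- function(layout, z) {
  if (!inherits(layout, "fgm_layout"))
    stop_stemopt("layout must be an fgm_layout", "invalid_parameter")
  if (any(z < -1e-9 | z > layout$length + 1e-9))
    stop_stemopt(sprintf("z outside [0, %.6g]", layout$length), "range_error")
  z <- clamp(z, 0, layout$length)
  # interval index counted from the distal end; boundary points go to the
  # higher (more proximal) interval, i.e. intervals are [b_i, b_{i+1})
  i <- findInterval(z, layout$boundaries, left.open = FALSE,
                    rightmost.closed = TRUE)
  i[i > layout$n_layers] <- layout$n_layers
  # distal interval 1 = layer n, proximal interval n = layer 1
  layout$moduli_gpa[layout$n_layers + 1L - i]
}

#' Read a material catalog or FGM schedule from YAML
#'
#' The YAML catalog maps names to `{modulus_gpa, poisson, ultimate_mpa}`;
#' an FGM schedule provides `{moduli_gpa, length, boundaries}`.
#'
#' @param path YAML file path
#' @return named list of [material()]s, or an [fgm_layout()] when the file
#'   contains a `moduli_gpa` key
#' @export
read_materials_yaml <- function(path) {
  if (!file.exists(path)) stop_stemopt("materials file not found", "file_error")
  y <- yaml::read_yaml(path)
  if (!is.null(y$moduli_gpa))
    return(fgm_layout(moduli_gpa = as.numeric(y$moduli_gpa),
                      length = y$length %||% 185,
                      boundaries = y$boundaries))
  out <- lapply(names(y), function(nm)
    material(nm, y[[nm]]$modulus_gpa, y[[nm]]$poisson %||% 0.3,
             y[[nm]]$ultimate_mpa %||% NA))
  names(out) <- names(y)
  out
}
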