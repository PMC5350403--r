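---
title: "Balancing stress shielding and cement damage in femoral stem design"
author: "stemopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing stress shielding and cement damage in femoral stem design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemopt)
```

## The design problem

A cemented total hip prosthesis fails over the long term through two
conflicting mechanisms. A stiff metal stem carries most of the load that the
proximal femur used to carry, so the surrounding cortical bone is
*stress-shielded* and resorbs. A compliant stem restores load to the bone but
raises the cyclic stresses in the PMMA cement mantle that fixes it, so
fatigue cracks nucleate in the cement and loosen the fixation. A good stem
design balances the two, and because both effects depend on the stem's
cross-sectional shape and size along its length, the balance can be sought
by shape optimization.

`stemopt` implements that workflow end to end at desk scale: a parametric
stem geometry, a structural surrogate of the femur--cement--implant
assembly, quantitative metrics for shielding and cement fatigue damage, and
a derivative-free global optimizer over the 20 geometric design variables.

## Parametric geometry

Each of the five variable cross sections (stations 2--6; the distal tip,
station 1, is a fixed circle of radius 6 mm) is a *two-half superellipse*

$$\left|\frac{x}{a}\right|^p + \left|\frac{y}{b}\right|^p = 1,$$

where the two halves share the medial--lateral semiaxis $b$ and the integer
exponent $p$, while the anterior half uses semiaxis $a_1$ and the posterior
half $a_2$. With $p = 2$ the section is an ellipse; $p = 3,4$ approaches a
filleted rectangle ("trapezoidal" in implant parlance). Four parameters per
station times five stations give the 20-variable design vector. Exponent
bounds per station are $[2,3]$, $[2,3]$, $[2,4]$, $[2,4]$, $[2,3]$
(distal to proximal); oval sections along the stem body keep the stress
distribution uniform while trapezoidal sections near the neck spread the
proximal cement load.

The stations ride on a skeleton: a straight prosthesis axis, a neck axis at
135$^\circ$ to it in the coronal plane, and a four-point Bezier spline that
flushes the sharp axis-to-neck transition. The boundary curves are lofted
with natural cubic splines through corresponding profile points, sampled on
a structured grid, and exported as watertight ASCII STL. Total length is
185 mm (150 mm axis + 35 mm neck).

Choices the method statement leaves open, fixed here and exposed as
configuration:

* **Half assignment.** Which semiaxis faces anterior is not determinate
  from the published sketch; the package fixes $a_1$ = anterior
  ($x \ge 0$). Swapping $a_1/a_2$ mirrors the section and changes no
  reported metric (the solver couples only through $A$ and $I_x$, both
  mirror-invariant).
* **Station placement.** Axis stations sit at fractions 0, 0.25, 0.55 of
  the total length, station 4 at the Bezier midpoint, stations 5--6 along
  the neck. Spacings are configurable (`stem_skeleton()`).
* **Neck angle** defaults to 135$^\circ$, a common caput-collum-diaphysis
  angle.

## Admissibility: the cement mantle

The design bounds themselves enforce the clinical mantle band: against the
default canal profile (circular, radii 8.5 / 9 / 10.5 / 12.5 mm at the four
in-bone stations), every semiaxis search interval is `canal - [3, 2]` mm, so
the mantle thickness measured along the principal semiaxis rays stays
between 2.0 and 3.0 mm. `check_constraints()` verifies exactly that band
along the anterior, posterior, medial and lateral rays, *plus* full angular
containment of the stem inside the canal, *plus* an insertability taper rule
(section areas nonincreasing from station 4 down to the tip). The band is
deliberately not applied at arbitrary angles: a trapezoidal section
($p > 2$) legitimately approaches a circular canal toward its corners, and
applying the band there would exclude the very trapezoids the method favors
near the neck. `cement_sections()` still reports the complete angular
thickness function for inspection.

## The structural surrogate

The reference workflow evaluates each design with a 3D tetrahedral finite
element model of a composite femur. That is replaced here by a deliberately
transparent 1D surrogate (the external stress-field import,
`import_stress_field()`, is the seam for users who have full FE results):

* The femur is an Euler--Bernoulli cortical tube, fixed distally, loaded
  proximally by the walking load case: a 2.5 kN joint contact force at
  10$^\circ$ from the femur axis (medial lever arm 45 mm) and a 1.5 kN
  abductor force at 15$^\circ$ (lateral lever arm 45 mm), together
  3.5 times a 700 N bodyweight. Cancellous bone is excluded.
* Over the implanted span the section is a fully bonded three-material
  composite (bone annulus, cement ring, stem). Strain compatibility gives
  one axial strain $\varepsilon_0 = N/\sum E_iA_i$ and one curvature
  $\kappa = M/\sum E_iI_i$ per section; each material sees
  $\sigma = E(\varepsilon_0 + \kappa y)$.
* The walking load is modeled as a zero-to-peak ($R = 0$) cycle, so the
  equivalent alternating and mean stresses both equal half the peak
  magnitude. The beam stress state is uniaxial, so the Von Mises reduction
  is simply $|\sigma|$.

Default surrogate femur: outer radius 12.5 mm along the shaft flaring to
16.5 mm at the resection plane, canal narrowest at the isthmus (8.5 mm,
where the stem tip sits) and flaring to 12.5 mm proximally -- a cortical
wall of 3.5--4 mm, typical of the arthroplasty population. These dimensions
were fixed once, at design time, so that the titanium reference assembly
reproduces the reported behavior of the full 3D model: a mean bone-surface
stress reduction in the implanted span in the 40--50 % range (the default
assembly computes to ~43 %; run `scripts/acceptance.R` or the example in
the README to reproduce the number).

Verification rests on closed forms rather than on the 3D reference: the
homogeneous limit (all moduli equal) must reproduce a monolithic femur to
$10^{-8}$, concentric circular composite sections must match the
transformed-section formula $\sigma_b = E_b(N/\sum EA + Mc/\sum EI)$ to
$10^{-8}$, and section resultants must integrate back to the applied loads.
Note the homogeneous limit compares against a *solid* intact femur: an
all-bone assembly tiles the entire cross-sectional disc, which equals the
intact tube only when the tube has no canal. The production intact
reference remains the hollow cortical tube.

## Fatigue damage of the cement

Per cement node (ring mid-thickness, every in-span axial station, 32
angles): the Goodman correction converts the (alternating, mean) pair to an
equivalent fully reversed amplitude
$\sigma_{eq} = \sigma_a/(1 - \sigma_m/\sigma_u)$ with $\sigma_u = 70$ MPa
for PMMA; the S-N curve $S = A N^b$ gives the life
$N_i = (\sigma_{eq}/A)^{1/b}$, clamped to the valid range (runout at
$10^8$ cycles); the node is damaged ($d_i = 1$) iff $N_i$ is *strictly*
less than the design life of $2 \times 10^6$ cycles (ties count as intact).
The **critical cement damage accumulation parameter** is the damaged
percentage $100 \sum d_i / i_{max}$.

The published source for the S-N data does not print coefficients; the
default $A = 90$ MPa, $b = -0.13$ is a log-log linear fit consistent with
published tension--tension PMMA cement fatigue data ($S(2\times10^6)
\approx 13.7$ MPa). Every damage result carries the curve used, and
`sn_curve()` / YAML configuration replace it freely.

A fidelity consequence worth stating plainly: the beam surrogate has no
stress concentrations, while real cement damage initiates at 3D features
(proximal mantle corners, the distal tip). Under the default walking load
the surrogate's cement stresses (1--4 MPa) sit below any credible PMMA
fatigue curve, so the titanium default computes 0 % damage. The damage
pipeline is therefore exercised by elevated-load configurations and by
generator fixtures with planted damaged fractions, and the optimizer's
damage term activates only when a configuration actually damages cement.
Absolute damage percentages from the surrogate should not be read as
predictions for a real femur.

## Metrics and the combined objective

The **stress shielding coefficient** compares equivalent alternating
stresses at $N = 3040$ matched surface locations (95 axial $\times$ 32
circumferential):

$$\mathrm{SSC} = \frac{1}{\sigma_{av}}
  \sqrt{\sum_{i=1}^{N} (\sigma_i - \sigma_i')^2},$$

with $\sigma_{av}$ the mean intact surface stress. It is nonnegative, zero
iff the fields agree, and scale-invariant. The typeset source formula is
ambiguous about the radical's scope; the root-sum-of-squares reading above
is the default and a sum-of-absolute-differences alternative is available
(`method = "abs"`). Both are tested.

The optimizer minimizes

$$f = \left(\frac{D}{D_{max}}\right)^2 +
      \left(\frac{\mathrm{SSC}}{\mathrm{SSC}_{max}}\right)^2,$$

where the normalization constants are the *running maxima* over all designs
evaluated so far (an `objective_state` environment shared across the run).
The objective therefore always lies in $[0,2]$, but a growing maximum
rescales earlier evaluations -- the JSONL log keeps the raw metrics so any
run can be renormalized post hoc. A term whose running maximum is still
zero (e.g. damage under the default load) contributes zero.

## The optimizer

A two-level Taguchi orthogonal-array search with probabilistic restarts:

1. Seed a store with 10 random vertices (each a full 20-variable design).
2. Select the stored vertex farthest from the rest: vertices normalized to
   the unit box, coordinates weighted by the store's per-coordinate
   variance, max--min weighted Euclidean distance (the appendix defining
   the original selection density is not available; this
   variance-weighted farthest-point rule is the package's documented
   interpretation, with plain max--min as a config alternative).
3. Around the selected vertex build two levels per variable:
   $x_i \mp 0.2\,\Delta x_i$ for the 15 continuous semiaxes
   ($\Delta x_i$ = domain width), $p_i \mp 1$ for the 5 integer exponents,
   box-projected into bounds.
4. Run the smallest two-level orthogonal array covering 20 factors (the
   32-run Sylvester--Hadamard array; balance and pairwise orthogonality
   are verified exhaustively in the tests), take per-factor main effects
   (mean response per level, smaller-is-better; a signal-to-noise variant
   is available), evaluate the predicted optimum, and fall back to the
   best evaluated run when factor interactions defeat the prediction.
   Repeat from the new point until the suggested optimum stops improving.
5. Add the local optimum to the store (unless already stored within
   tolerance) and restart, up to 30 restarts.

One reading the package had to fix: optima are stored "to avoid selecting
the same experiments", but a bare farthest-vertex rule re-selects the same
extreme start on every restart, collapsing the search to one local optimum.
Here a vertex may seed at most one restart; it stays in the store so its
neighborhood keeps repelling later selections. On a 5-variable sphere
benchmark (10 restarts) this makes every tested seed reach the global
minimum to within 0.05, which is also the acceptance bar.

Inadmissible geometry encountered inside an array receives the penalized
objective $2 + \text{violation magnitude (mm)}$ rather than aborting, so
arrays stay complete and main effects remain estimable.

## Functionally graded stems

The graded stem is sliced into 11 equal lengthwise layers with
piecewise-constant modulus 120, 110, 90, 80, 70, 60, 50, 40, 30, 20, 10 GPa
from proximal to distal (Poisson's ratio 0.3 throughout; boundary points
belong to the more-proximal layer). The layers span the full 185 mm stem,
so the in-bone portion sees layers 3--11 -- where the proximal layer starts
depends on the resection level, which the source does not dimension. The
source also states the proximal layer matches Ti-6Al-4V (110 GPa) while its
schedule tabulates 120 GPa; the tabulated value is the default and
`fgm_layout(layer1_gpa = 110)` switches readings. Because the graded
modulus is everywhere at most the titanium modulus inside the bone, the
graded stem's bone-surface stresses are pointwise at least the titanium
stem's, hence its shielding coefficient is provably smaller on the same
geometry -- the tests assert exactly that.

## Synthetic data generators

The `make_*` generators exist so every module is testable without any
external data, and they define the package's test conditions:

* `make_surrogate_femur()` -- plain or tapered cortical tubes.
* `make_stress_pair()` -- intact/implanted surface fields with a planted
  per-station reduction and optional multiplicative noise, giving the
  shielding coefficient a known ground truth.
* `make_cement_field()` -- cement stress fields drawn log-uniformly from
  1--50 MPa (the range over which the default S-N curve produces mixed
  damage), optionally with an exact planted damaged-node count, placed by
  inverting the S-N curve around the design-life stress.

All generators are pure functions of their parameters and seed. What they
do *not* emulate: spatial correlation of 3D FE fields, multiaxial stress
states, and interface stress concentrations -- so green tests demonstrate
correctness of the formulas and the optimizer on the surrogate's physics,
not predictive accuracy for a cadaveric or clinical femur.

## Numerical choices

* Section properties: Green's-theorem polygon formulas on a 2048-gon with
  Richardson extrapolation against the 4096-gon, giving ~$10^{-11}$
  relative accuracy on circles (tested against the superellipse
  gamma-function closed form $4ab\,\Gamma(1+1/p)^2/\Gamma(1+2/p)$ at
  $10^{-4}$).
* Stem section properties are interpolated linearly in $z$ between the
  four in-bone stations; station 4 is projected onto the resection plane
  for the 1D solver (the Bezier region's centerline offset is a few mm and
  is neglected by the beam model).
* Axial sampling uses cell centers, $z_k = (k - \tfrac12)L/n$, avoiding
  the ambiguous end sections.
* Strict-inequality damage rule; ties at the design life count undamaged.
* Duplicate optima are detected at $10^{-6}$ in the unit box; selection
  ties break toward the lowest store index; a single seeded RNG drives the
  whole optimization.
* Problem sizes in the shipped tests are chosen for a laptop-class run:
  solver grids of 20 x 8 to 40 x 16 in unit tests, the full 95 x 32 grid
  for the configuration-fidelity and shielding checks, and optimizer smoke
  runs with 4 initial vertices / 2 restarts (the full-scale 10/30 run is
  the configured default of `run_optimize()`).

## Known limitations

* The 1D composite-beam surrogate cannot reproduce torsion, shear-driven
  interface stresses, hoop stresses in the mantle, or any stress
  concentration; absolute damage percentages are not comparable with 3D FE
  values (import externally computed fields for that).
* The canal is circular/elliptic per station and fixed during
  optimization; a broached, stem-shaped cavity is not modeled.
* Single-amplitude loading only: no load spectra, no linear
  damage-accumulation bookkeeping across blocks, no crack propagation.
* The stress shielding coefficient aggregates over the whole surface; no
  per-Gruen-zone summaries.

## A minimal run

```{r example, eval = FALSE}
cfg <- default_config()                  # titanium stem, 95 x 32 grid
dv <- mid_design()                       # documented default design
check_constraints(dv, cfg$canal)         # admissible, 2.5 mm mantle

res <- run_evaluate(dv$values, cfg)
res$reduction$overall                    # mean stress reduction, %
res$ss_coef                              # stress shielding coefficient
res$damage_pct                           # cement damage parameter, %

# small optimization (full scale: n_init = 10, max_restarts = 30)
cfg$n_axial <- 20; cfg$n_circ <- 8
cfg$optimizer$n_init <- 4; cfg$optimizer$max_restarts <- 2
opt <- run_optimize(cfg, out_dir = tempdir())
opt$best$objective
```
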