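---
title: "Methods: a desk-scale design loop for porous titanium reconstruction plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale design loop for porous titanium reconstruction plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Reconstruction of a segmental mandibular defect relies on a titanium plate
that must carry occlusal loads safely while staying as light and as
compliance-matched to cortical bone as possible — a too-stiff implant
shields the bone and drives resorption, a too-soft one risks yield and
screw loosening. Additively manufactured Ti-6Al-4V lattices let the designer
tune stiffness through porosity, but every candidate geometry needs a finite
element (FE) verdict, and exhaustive FE sweeps are too slow for interactive,
risk-aware design. `latticeplate` implements the whole loop at desk scale:

1. calibrate a porosity–stiffness law from lattice-coupon measurements;
2. mesh a parametric synthetic bone–plate–lattice construct;
3. solve linear-elastic equilibrium and extract three mechanical targets;
4. sweep a design of experiments and train a neural surrogate;
5. propagate bone, load and build scatter by Monte Carlo into exceedance
   probabilities; and
6. search the design space with a risk-constrained multi-objective genetic
   algorithm.

Everything runs from a single run configuration,

```{r}
library(latticeplate)
cfg <- validate_config(list(outdir = "run"))
out <- run_pipeline(cfg)
```

or stage by stage through `run_stage()` / the `inst/cli/latticeplate`
script.

## Material model

Dense Ti-6Al-4V (ELI) is carried as a material card with E = 110 GPa,
nu = 0.33, rho = 4.43 g/cm^3, sigma_y = 880 MPa, sigma_u = 950 MPa;
cortical bone as E = 13 GPa, nu = 0.30. The homogenised lattice follows the
Gibson–Ashby open-cell power law

E_eff(p) = C · E_s · (1 − p)^n,

fitted by least squares on the log scale to four coupon measurements
(porosities 4.1–37.1%, moduli 89–35 GPa). The model form is the package's
choice: the calibration data alone constrain only a monotone decay, and the
open-cell power law is the standard constitutive choice for strut lattices.
The prefactor C is left free rather than pinned at 1 because the coupon
data are matched noticeably better that way; predictions are clipped at
E_s. On the built-in table the fit gives C ≈ 0.883, n ≈ 2.23 with a
log-scale R² above 0.998, and reproduces every coupon modulus within 10%.

Strut diameter d and unit-cell size a map to porosity through a
relative-density model rho_rel = k (d/a)^2 with the simple-cubic-strut
coefficient k = 3π/4 by default. The source geometry is a graded gyroid for
which no density formula is published, so the coefficient is an explicit
`lattice_cell()` field that other topologies can replace. Slenderness
d/a > 0.5 means struts merge; such designs are flagged infeasible and
removed by the DOE quality filter rather than silently clipped.

## The synthetic construct and its mesh

The patient geometry is replaced by a prismatic surrogate that preserves
the load path of a plated, grafted defect: two cortical-bone end blocks
(25 mm each) bridge a 30 mm defect span; the lower part of the span is
treated as grafted bone (assigned the cortical card, consistent with a
consolidated fibula graft); an implant stack runs along the full top
surface — two solid Ti face plates of thickness t_plate sandwiching a
homogenised lattice core of thickness t_lat. Discrete screw columns (eight
by default, at four axial stations) tie the stack through the bone blocks.
Both outer faces are fully constrained ("condylar" ends) and the occlusal
bite force (300 N soft diet / 600 N clench) is applied as a uniform
pressure patch, 8 mm wide, centred over the defect.

The mesh is a structured grid of 8-node trilinear hexahedra with grid lines
on every material interface, so each element carries exactly one region
label and region volumes partition the prism exactly. Hexahedra were chosen
over the quadratic tetrahedra a commercial solver would use because the
structured grid admits closed-form verification (patch test, bar,
cantilever) and deterministic refinement; the equilibrium problem itself is
element-agnostic. All interfaces are bonded (shared nodes): a linear model
is what the observed exact load-proportionality of the responses implies,
and it keeps the stiffness operator strictly linear in each region modulus —
a property the sweep exploits by assembling unit-modulus region matrices
once per mesh and re-weighting them per design.

Integration is full 2×2×2 Gauss; stresses are evaluated at the integration
points from the constitutive law and volume-averaged per element; plate
stresses are additionally averaged over the through-thickness column of
plate elements sharing an (x, y) footprint before the maximum is taken,
which suppresses spurious surface singularities at the screw stations. The
three reported targets are the peak thickness-averaged plate von Mises
stress (MPa), the peak nodal displacement magnitude (mm), and the peak
screw-region von Mises stress (MPa).

### Mesh density

The canonical divisions (8/12 axial elements per bone block/span, 5 across
the width, 4+2+3+2 through the thickness; 1540 elements) were fixed by the
package's own convergence ladder: refining every division by 20% changes
the peak thickness-averaged plate stress by about 1.5%, inside the 3%
acceptance band, while a coarser grid fails it. `convergence_study()`
reproduces this ladder on any configuration. Trilinear hexahedra are
bending-stiff at low density, so displacement converges more slowly than
the thickness-averaged stress; the documented density is a deliberate
trade-off that keeps the 1440-solve sweep around five minutes on one CPU.

## Design of experiments

The canonical training corpus is the full factorial over
d ∈ {0.40, 0.55, 0.70, 0.85, 1.00, 1.15} mm, a ∈ {2.0 … 4.0} mm,
t_lat ∈ {1.5 … 4.5} mm, t_plate ∈ {1.0, 1.5} mm and P ∈ {300, 600} N —
480 runs, of which the 16 strut-merging combinations (d/a > 0.5) are
excluded by QC together with any non-converged solve. A Latin-hypercube
generator (`latin_hypercube()`, stratification delegated to the `lhs`
package) is available for users who prefer space-filling designs or extra
variables. Because bone-modulus scatter cannot travel through a surrogate
that never saw it, the sweep is augmented with a sixth factor, the
bone-modulus multiplier at levels {0.8, 1.0, 1.2}, and a second, six-input
surrogate is trained for the risk pathway; the five-input surrogate trained
on the multiplier-1 subset is the one whose metrics are reported.

## Surrogate

The surrogate is a multi-output multilayer perceptron, 64–32–16 hidden
units, ReLU activations, linear 3-unit output, He initialisation, dropout
0.10 after the first two hidden layers, L2 weight decay 1e-4 — written in
plain R because no pre-installed package provides this training protocol,
and because the surrogate is the scientific core of the package rather than
a commodity step. Training uses Adam (lr 1e-3, beta1 0.9, beta2 0.999,
eps 1e-8), batch size 64, Huber loss with delta 1.0 (mean-squared error by
switch), early stopping on validation MAE with patience 80 and a 2000-epoch
cap, restoring the best-validation checkpoint. The split is 70/15/15
stratified over the load and plate-thickness levels; within each stratum
rows are allocated by largest remainder so proportions match within one
row.

Inputs are z-scored with training-split statistics. Targets are not
log-transformed; internally they are also z-scored during optimisation
(inverted at prediction) so that the Huber transition acts on a comparable
scale for MPa- and mm-valued outputs — without this, delta = 1.0 would mean
something different for each output. The backward pass is verified against
finite differences in the test suite, and training is bit-reproducible
under the configuration seed.

A zero-mean Gaussian residual model per output, with sigma equal to the
untouched test split's RMSE (floored at a machine-scaled epsilon), feeds
the risk stage. A quadratic response surface (`poly_baseline()`, ordinary
least squares on the same standardized inputs) is fitted alongside as the
classical baseline and reported with the same metric contract.

## Risk model

Input scatter is a factorised graph of independent root nodes: bone-modulus
scale ±20%, bite-force scale ±30%, build-porosity offset ±5 percentage
points. "±x" is read as a uniform factor/offset — bounded and
assumption-light, since the scatter families are not otherwise specified —
with a normal alternative (±x as a 95% interval) by configuration. With no
observed nodes to condition on, forward Monte Carlo sampling of the
factorised joint is the operative computation, and that is what
`sample_joint()` does, 10 000 samples by default.

Per sample, the load is scaled, the porosity offset is mapped back to an
equivalent strut diameter (the surrogate's porosity carrier) through the
inverse of the relative-density model, and the bone multiplier enters the
sixth input; the surrogate predicts the three targets, residual noise is
added, and exceedance indicators are accumulated. The reported
probabilities are Pr(sigma_vM,max > sigma_allow), Pr(sigma_vM,max >
0.9 sigma_y) and Pr(delta_max > 1 mm), each with the binomial standard
error. Defaults: sigma_allow = 0.9 × 880 = 792 MPa, displacement limit
1 mm, acceptance cap 3%. The Monte-Carlo estimator is validated against
the closed-form normal tail on an exactly linear surrogate in the test
suite, and `verify_against_fem()` re-solves the FE chain at sampled
perturbations to bound the surrogate discrepancy directly.

## Optimisation

`run_ga()` is an NSGA-II-style search: binary tournament on
constraint-dominated rank and crowding distance, simulated-binary crossover
(eta 15), polynomial mutation (eta 20, rate 1/n). Objectives: implant mass
(face plates plus lattice at relative density 1−p over the envelope,
minimised), peak plate stress (minimised), and fatigue margin
340 MPa / sigma_vM,max (maximised; 340 MPa is the endurance limit of the
HIPped alloy). The risk probability acts as a constraint through
constraint domination — any feasible candidate dominates any candidate
whose risk exceeds the 3% cap, and infeasible candidates rank by violation
— with the geometric d/a cap folded into the same violation. The search
runs on the continuous hull of the factorial levels with the load fixed at
the 600 N worst case. All feasible evaluated candidates accumulate in an
external archive and the returned Pareto set is the non-dominated subset of
that archive, so longer runs can only improve it; the final report stage
re-audits every member at 10 000 fresh-seed samples.

The optimisation-efficiency index condenses the landscape into one score:
the weighted (default 0.5/0.5), min–max-normalised combination of mass
saving relative to each design's fully solid counterpart and stiffness
matching −|E_construct − 13 GPa|, where E_construct converts the solved
midspan deflection through the fixed-fixed centre-loaded beam formula
E = P L³ / (192 δ I). A final min–max pass pins the evaluated set's best
design at exactly 1 and its worst at 0. The concrete form is the package's
own definition — only the ingredients (stiffness gain versus mass
reduction) are inherited — so no numeric agreement with any external
per-cell score is claimed, only the structural features: scores normalise
to [0, 1] and porosity-binned summaries expose the interior optimum.
`trend_regression()` supplies the slope/R²/p summaries used to describe
how elastic strain (100 · sigma_ref / E_eff at the 50 MPa reference) and
efficiency move with porosity.

## Reproducibility and seeds

A single global seed drives everything. Stage seeds derive as
`(seed · 97 + 13 · stage_index) mod (2³¹ − 1)`, so any stage can be rerun
in isolation; datasets, checkpoints and fronts round-trip through plain
CSV/JSON; the pipeline is byte-reproducible under a fixed seed (asserted in
the tests at reduced scale). The Pareto audit deliberately uses a fresh
seed per member so that the in-loop risk estimate cannot audit itself.

## What the synthetic benchmark does and does not show

The generator reproduces the study conditions — material constants, coupon
calibration, factorial levels, load cases, scatter magnitudes, thresholds —
on a geometry that preserves the load path but none of the anatomy. Passing
tests therefore demonstrate that the machinery is correct (exact linearity,
mesh convergence, surrogate fidelity on its own FE data, calibrated risk,
dominance-sound archives), not that any absolute stress or displacement
matches a patient-specific mandible: peak values on the prism are a few
tens of MPa where the anatomical model reports hundreds, because the
synthetic cross-section is stockier and the load path straighter. Claims
tied to CT geometry, printing, or physical testing are out of scope.

## Known limitations

- Linear elasticity with bonded interfaces: no contact, friction,
  plasticity, or fatigue-cycle simulation.
- The homogenised lattice is isotropic; strut-level stress concentrations
  and print anisotropy are invisible to it.
- Scatter nodes are independent; correlated bone/load variation is not
  modelled.
- Trilinear hexahedra lock in slender bending; the documented mesh density
  compensates, but very thin face plates (below ~0.5 mm) would need a finer
  through-thickness grid than the default.
- The efficiency index is intentionally simple; it is a reporting device,
  not an objective of the search.
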