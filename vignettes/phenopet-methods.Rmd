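---
title: "phenopet: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenopet: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`phenopet` simulates the growth of a solid tumor in vascularized normal
tissue at cellular resolution, renders the resulting cell maps as noisy
PET-like images, and quantifies how well texture radiomics can tell
microscopically distinct tumor phenotypes apart. It is a hybrid multiscale
model: a lattice of discrete agents (blood-vessel cross-sections, normal
cells, and tumor cells that are normoxic, hypoxic or necrotic — exactly one
agent per 20 µm pixel) is coupled to two continuous reaction–diffusion
grids carrying oxygen and glucose.

The nutrient fields obey Fick diffusion with cellular consumption,

$$\partial C/\partial t = D\nabla^2 C + f,$$

with periodic boundary conditions (the grid is a section of a larger
tissue) and vessels acting as Dirichlet sources clamped at vascular
concentrations (50 mmHg oxygen, 5 mM glucose). Glucose consumption is
Michaelis–Menten, $f = -V_{max}[S]/(K_M+[S])$, with class-specific
$V_{max}$; oxygen consumption is the constant-rate limit of the same law
because tissue $K_M$ for oxygen is negligible against tissue
concentrations. Necrotic cells and vessels consume nothing.

Each cell produces ATP from both pathways,
$f_{ATP} = 2 f_G + (27/5) f_O$ (glycolysis yields 2 ATP per glucose;
aerobic respiration ~27 per glucose at 5 O~2~ per glucose), and the hourly
per-cell decision sequence is: survival, then oxygenation classification,
then division.

* **Survival.** A cell risks necrosis when local oxygen falls below
  0.08% O~2~ or the ATP production rate falls below
  2.57×10⁻¹⁴ mol/min/cell. The per-hour death probability is
  $1-(\text{local}/\text{threshold})^x$, evaluated once per criterion with
  one uniform draw each; the oxygen exponent is 1 for all phenotypes and
  the ATP exponent is a phenotype microparameter (1 or 2). There is no
  separate "prolonged exposure" timer: the hourly probabilistic draw is the
  model's realization of prolonged-exposure risk.
* **Oxygenation.** Hypoxic iff oxygen lies in the closed band 0.08–0.5%
  O~2~; above the band the cell is (re)classified normoxic. Transitions are
  bidirectional. Survivors below the band remain hypoxic.
* **Division.** A viable cell with both quantities at or above their
  thresholds divides with hourly probability
  $(1/24)\min(1, C_{O_2}/C_{0.5\%})$, so normoxic cells average one
  division per 24 h and hypoxic cells scale linearly with oxygen. The
  daughter takes a uniformly chosen NORMAL pixel of the Moore
  8-neighborhood; if none exists, a VESSEL neighbor is replaced with the
  phenotype's vessel-removal probability, otherwise the division is lost.
  Daughters inherit the parent's state and are re-classified at the next
  hourly pass from their own local oxygen.

Six phenotype presets A–F vary four microparameters: vessel density
(20–100 mm⁻²), vessel pattern (uniform-random pixels, or a square lattice
with ±25% jitter — the jitter law is a package choice, bounded so that
near-uniform density is preserved), vessel removal probability, and the ATP
death exponent.

## Unit conventions

The model is 2D; per-cell molar rates (mol/min/cell) become concentration
sinks through an effective pixel volume $V_{pix} = (20\,µm)^2 \times
20\,µm$, a unit-depth slab equal to the cell size (configurable via
`pixelDepth`). Oxygen is tracked in mmHg with 1% O~2~ = 7.6 mmHg and a
Henry-law solubility of 1.3×10⁻⁶ mol/(L·mmHg) — the standard value for
tissue at 37 °C — converting molar consumption to mmHg/s. With these
conventions the model predicts anoxia roughly 160 µm from an isolated
vessel at tumor consumption rates, the classical histological figure,
which we take as the main justification for the solubility choice.

The glucose Michaelis constant is configurable with default 0.5 mM, a
mid-range literature value for cellular glucose uptake; the constant
appears in some parameter tables with rate units, which cannot be used as
a concentration, so the package treats it as its own named parameter.

## Numerics

The diffusion solver is explicit FTCS with the 5-point Laplacian. The
unitless number $D\,\Delta t/\Delta x^2$ must stay ≤ 0.25; the defaults
(30 ms steps at 20 µm) give 0.124 for oxygen and 0.020 for glucose, and
the package refuses unstable configurations by name. Two facts keep full
growth runs affordable without changing any result:

1. **The FTCS fixed point is independent of $\Delta t$** (the time step
   cancels from $\alpha \nabla^2 C = \Delta t\, f$), so `runGrowth`
   relaxes at the stability bound ($\alpha = 0.2$) by default. A property
   test verifies that halving $\Delta t$ moves the steady state by less
   than 0.1%.
2. **Perturbations are screened within about one vessel spacing**, because
   vessels clamp the field. Hourly re-relaxations therefore sweep only a
   box around the tumor (30-pixel margin by default) with frozen boundary
   values, warm-started from the previous hour and capped at 400 steps per
   field per hour; residuals carry over quasi-statically between hours.
   The initial relaxation, and all calls to `relaxToSteadyState` outside
   the growth loop, sweep the full grid to convergence.

Convergence is declared when the maximum per-step fractional change,
scaled by $1/(1-\hat\rho)$ with $\hat\rho$ an online estimate of the
slowest mode's decay rate, falls below `tol` (default 10⁻⁵). The scaling
makes `tol` a bound on the residual distance to the fixed point rather
than on the step size; without it, two relaxations started from different
fields can both "converge" while still differing by far more than `tol`,
and the initialization-independence property would fail. Concentrations
are floored at zero and vessels re-clamped after every step.

Update order within an hour is a fresh random permutation of viable tumor
cells, avoiding directional growth bias; normal cells do not proliferate
(the model has no healthy-cell turnover rule). All randomness flows
through R's RNG, so `set.seed` (or the seed in a `PhenotypeConfig`) fixes
trajectories bit-identically, and `resumeGrowth` restores the serialized
RNG state to continue a run exactly.

## PET synthesis

Cell maps convert to pseudo-SUV (pSUV) by class: necrotic 0, normal 1,
normoxic tumor 8, hypoxic tumor 12 (8× normal uptake, and 1.5× that for
hypoxic cells). Vessels map to 1 — blood pool at background — a package
convention, since the four-class mapping leaves them unassigned.

The acquisition chain center-crops (or pads with pSUV 1, i.e. normal
tissue) the world to the 68 × 0.58 mm = 39.44 mm field of view,
block-averages 29×29 cell pixels per reconstruction pixel, applies an
image-space Gaussian PSF (2.0 mm FWHM), forward-projects with a sparse
pixel-driven parallel-beam projector (180 angles over 180°, 0.58 mm
detector bins), scales to expected counts with a single global factor (the
acquisition-time surrogate), Poisson-samples unless noise-free, and
reconstructs with OSEM (8 subsets × 4 iterations, matched adjoint,
non-negative by construction). A small post-reconstruction Gaussian
(1.22 mm) is tuned so the end-to-end point-source FWHM is 2.35 mm ± 5%;
a test measures this on a reconstructed point source. Projector and OSEM
settings are deliberately the minimal standard tomographic setup and are
all exposed in `acquisitionSettings()`.

Noise is quantified as NSTD (std/mean) over the central 40% × 40% of a
uniform reference phantom at pSUV 2.37 (average liver uptake).
`calibrateNoise` adjusts the count scale until the phantom reconstructs at
a target NSTD, iterating the Poisson scaling law NSTD ∝ 1/√scale on
averages of ≥10 phantom realizations until within 2% relative. The NSTD of
a single realization has ≈6% relative sampling scatter, so any comparison
of a measured NSTD against its target at fixed realization count must
budget for the standard error of that mean; the acceptance test does so
explicitly.

## Radiomics protocol

Features are computed inside ground-truth lesion masks (tumor support
resampled to the reconstruction grid; a pixel is in the mask iff its
tumor-area fraction is ≥ 0.5), with no image resampling and no intensity
normalization. Intensities are quantized with a fixed bin width of 0.5
pSUV anchored at the masked minimum; gray levels are contiguous from 1.
The GLCM uses distance 1, counts only pairs with both pixels in the mask,
and pools the four 2D directions symmetrically before a single
normalization (the 2.5D direction-merged protocol collapsed to 2D for
single-slice images). All 22 Haralick features use base-2 logarithms with
0·log 0 = 0. Degenerate single-level masks return correlation and the
IMC-type features as 0 with a flag; growth snapshots never hit this case
but synthetic tests do.

Discrimination statistics use the Welch unequal-variance two-sample t
statistic by default (a pooled-variance option exists; the choice is
recorded in the output's metadata), significance flagged at p < 0.01 with
no multiple-testing correction, mirroring the per-cell presentation of the
reference tables. Cluster separation uses the silhouette score (via the
cluster package) and a Calinski–Harabasz criterion computed from its
definition; both are cross-checked against scikit-learn in the tests.

## Scaled study conditions

The full-scale experiment — a 2000×2000 grid (4×4 cm) grown from one cell
to 1.7 cm over five realizations per phenotype — is supported but takes
hours per run. The shipped tests and the acceptance script use scaled
study conditions chosen to preserve the measured quantities:

* steady-state tissue concentrations use 500×500 grids (1 cm²), which are
  already self-averaging for vessel densities 20–100 mm⁻²;
* growth-dependent quantities use 250–280 pixel grids grown to 2.0–2.2 mm
  diameter, one realization per phenotype (the test suite) or one per
  phenotype with script-seeded RNG (the acceptance script). Tumor-tissue
  nutrient averages at these sizes sit inside the printed one-standard-
  deviation bands of the full-scale values, which is what the acceptance
  checks assert; the linear diameter–time law makes growth-rate
  comparisons scale-free.

One consequence of the scaled conditions is worth stating: texture is
only measurable for lesions several resolution units across. A 2 mm
tumor spans about a dozen reconstruction pixels and, after 2.35 mm
blurring, less than one 0.5-pSUV quantization bin of contrast, so its
GLCM collapses to a single gray level — the same resolution limit that
makes features informative only above roughly 5 mm at full scale. The
noise-response checks therefore run on shipped 10 mm structured lesion
phantoms (`makeFixture("lesion-cored")`, `"lesion-speckled"`,
`"lesion-rimmed"`) rather than on the 2 mm scaled growth runs; the
phantoms isolate the property under test (the imaging and feature chain)
from growth-run cost.

Because growth is linear in diameter over time, the full-scale times to
1 cm can be compared against `growthTimesToOneCmDays()` from a scaled
run's slope. A full-scale phenotype-A run
(`runGrowth(phenotypePreset("A"), stopDiameter = 10)`) is documented but
not part of any shipped test; extrapolating the scaled phenotype-A slope
lands within the inter-phenotype spread of the reference times
(96–258 days).

## What the generator does and does not emulate

The synthetic worlds reproduce: point-source vasculature of controlled
density and pattern, nutrient-limited growth with hypoxic layering and
necrotic cores, phenotype-specific morphology (solid, uniform-necrotic,
tendril-like), realistic PET resolution/noise, and longitudinal snapshot
series. They do not emulate: mechanical forces or tissue resistance,
angiogenesis, necrotic clearance, apoptosis, cell migration, tracer
kinetics (uptake is a static per-class value), attenuation/scatter/randoms
in the acquisition, or 3D geometry. Passing tests therefore validate the
model's internal consistency and its agreement with the reference
quantities, not clinical realism of any individual image.

## Known limitations and edge cases

* Vessels are point cross-sections with no geometry or elasticity.
* The oxygen solubility, pixel-depth volume convention and glucose
  $K_M$ are package choices (defaults above); they are exposed as
  parameters precisely because the 2D model leaves them under-determined.
* Seeding the initial tumor cell on a vessel replaces the vessel with a
  warning (the single initial cell must exist).
* Hypoxic survivors below the hypoxia band are classified hypoxic; the
  band itself is closed on both ends; necrosis is evaluated strictly
  below threshold.
* A tumor whose every viable cell dies is an "extinct" run — a legitimate
  terminal state, not an error.
* The FOV (39.44 mm) is 0.56 mm smaller than the default world (40 mm);
  the world is center-cropped before projection.
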