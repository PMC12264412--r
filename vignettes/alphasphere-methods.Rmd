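---
title: "Methods: multicellular alpha-particle dosimetry and tumor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicellular alpha-particle dosimetry and tumor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`alphasphere` models targeted alpha therapy (TAT) at the scale where it is
decided: single cell nuclei inside a multicellular tumor spheroid. Alpha
particles travel 40–110 µm in tissue — a few cell diameters — so the dose a
nucleus receives depends on where, within each cell, the radionuclide sits
(membrane, cytoplasm, whole cell, or nucleus), on how activity fluctuates
from cell to cell, and on how much cross-fire arrives from neighboring
cells. The package simulates this chain end to end: spheroid construction,
decay placement, simplified alpha transport, per-nucleus energy bookkeeping,
and the biophysical endpoints used to compare treatment scenarios — cell
survival, tumor control probability (TCP), relative biological effectiveness
(RBE), and the activity per cell (APC) or spheroid dose required to reach
TCP = 0.9.

# The irradiated system

## Spheroid construction

`generate_spheroid()` builds a `cell_population`: spherical cells with a
concentric spherical nucleus, packed into a spheroid of the requested radius
and *compaction*, defined operationally as the fraction of the spheroid
volume covered by the union of the cell spheres. The packing contract is:

* nuclei are pairwise disjoint, hard constraints enforced by deterministic
  overlap relaxation and verifiable with `max_nucleus_overlap()`;
* every nucleus lies entirely inside the spheroid; cytoplasm spheres may
  overlap each other and may protrude through the spheroid surface;
* nucleus radii may shrink, uniformly, down to 80% of the cell line's
  maximal nucleus radius (the same floor mesh-based spheroid generators
  use), and cell radii may shrink uniformly, never below the nucleus radius,
  when the compaction target requires it.

Two deliberate approximations replace membrane-mesh deformation. First,
overlapping cytoplasm stands in for deformed, truncated cytoplasm: since the
whole medium is liquid water at 1 g/cm³, membrane shape influences only
where decays start, not how particles propagate. Second, nuclei are
pre-shrunk before placement whenever their packing fraction would exceed
0.25. This choice is not cosmetic: relaxing *full-size* nuclei at high
density drives the centers toward an ordered, near-jammed arrangement whose
cell spheres cover the spheroid far more efficiently than a random
arrangement does, which simultaneously distorts the cell count, the
cross-fire fraction and the spheroid dose of the dense reference system.
Pre-shrinking keeps the relaxed centers close to a minimally correlated
(random sequential) arrangement; at low compaction the criterion leaves
nuclei at full size, and an isolated cell keeps the nominal 5.5/6.9 µm
OVCAR-3 geometry exactly.

The generator searches the cell count with a coverage model
(`union fraction ≈ 1 − exp(−N v_eff)`, re-estimated from each Monte Carlo
measurement), then fine-tunes by uniform cell-radius shrink if it overshoots.
The achieved compaction is reported with its binomial standard error from
hit-or-miss integration (`estimate_compaction()`, spatial-hash accelerated);
generation fails with the achieved value in the message when the target
cannot be approached within 0.03. A single-cell request (spheroid radius
equal to one cell radius) degenerates to one cell at the origin and skips
the tolerance check, since no sparser population exists. Identical seeds
reproduce populations bitwise.

## Cell lines

`cell_line()` carries the geometry (maximal nucleus/cell radii, µm) and the
reference photon linear-quadratic coefficients: HSG (6.7/7.3 µm,
α = 0.313 Gy⁻¹, β = 0.062 Gy⁻²), V79 (5.2/7.1, 0.184, 0.020), CHO-K1
(3.85/7.0, 0.228, 0.020), and OVCAR-3 (5.5/6.9, geometry only — by
convention it is paired with the HSG coefficients, which is exactly what the
default reference configuration does).

# Sources

## Radionuclides

Decay data ship as a structured YAML file (`inst/extdata/nuclides.yaml`)
with user files accepted in the same schema. The default emitter is
At-211: a 5.87 MeV alpha in 41.8% of decays, and in the remaining 58.2% an
electron-capture branch to the 0.516 s daughter Po-211 whose 7.45 MeV alpha
is sampled as part of the parent's spectrum (one alpha per decay either
way). Po-210 (5.304 MeV, 138.4 d) and Po-213 (8.376 MeV dominant) bracket
the alpha-energy range. Beta, gamma and X-ray emissions are deliberately out
of scope: their ranges are so much larger than a spheroid that they add a
nearly uniform background which cancels from every distribution comparison.

Activity per cell converts to cumulated decays under instantaneous uptake
and complete decay: `N = A₀ t_1/2 / ln 2` (`activity_to_mean_decays()`), so
1.12 mBq of At-211 is 42 decays and 0.40 mBq is 15. Emissions are isotropic;
energies follow the line intensities.

## Intracellular distribution and intratumoral fluctuations

`place_decays()` samples decay positions uniformly on the membrane sphere,
in the cytoplasm shell, in the nucleus ball, or in the whole cell ball.
Because cytoplasm spheres overlap in our geometry, a sampled position can
fall inside a *neighbor's nucleus*; nuclei are impenetrable organelles, so
such positions are redrawn (bounded retries). Positions inside a neighbor's
cytoplasm are accepted, consistent with the overlap approximation.

Cell-to-cell activity fluctuations (`activity_model()`) are either uniform —
every cell gets the rounded mean decay count — or lognormal with shape
factor σ (default 2.0, the value that reproduces published uptake
measurements at full labeling). The lognormal is parameterized
mean-preservingly, `meanlog = ln(APC) − σ²/2`, so its arithmetic mean equals
the requested APC and the spheroid-level expected decay count matches the
uniform case; continuous activities become integers by stochastic rounding
(floor plus a Bernoulli on the fractional part), which preserves the
expectation exactly.

## Daughter diffusion

For the 58.2% of At-211 decays routed through Po-211,
`apply_daughter_diffusion()` draws the daughter's decay time from its
exponential law and displaces the emission point by thermal diffusion:
Gaussian per axis with standard deviation √(2Dt) (mean squared displacement
6Dt), or a single Gaussian step along a random direction (2Dt) for the
strictly one-dimensional variant; both are exposed because the original
treatment is ambiguous on this point. The diffusion coefficient is a
configuration value (default 1000 µm²/s, the 10⁻⁵ cm²/s scale of small
solutes in water) — no published value exists for this system, so diffusion
results must always be read against the configured D. Constraints follow
the bound/free picture: intracellular daughters cannot leave their original
compartment, membrane daughters diffuse in the intercellular space without
entering any cell; both are enforced by bounded rejection with a radial
reflection fallback (membrane daughters fall back to their original surface
point).

# Transport

Alphas travel in straight lines under the continuous-slowing-down
approximation (CSDA). Lateral deflection of multi-MeV alphas is far smaller
than a cell, and published sensitivity of the mean specific energy to the
underlying physics model is on the percent scale, so curvature and
energy-loss straggling are omitted. Secondary electrons deposit locally on
the path, which realizes exactly the charged-particle-equilibrium
bookkeeping `deposit = E_entry − E_exit` used by the survival models.

The range–energy relation ships as a dense table (0.01–12 MeV, 1200
log-spaced knots) for liquid water, computed by integrating Bethe stopping
power with a Barkas-type effective-charge correction (I = 75 eV) and
normalized once to the evaluated 113 µm CSDA range at 10 MeV; the 5.304 and
8.376 MeV anchors (~40 and ~84 µm) serve as validation. The derivation
script is `tools/make_range_table.R`. Run-time interpolation is linear on
the dense grid in both directions — strictly monotone, with `range(0) = 0`
and linearity through the origin below the first knot — and the identical
interpolation runs in R (`csda_range()`, `residual_energy()`) and in the
C++ tracer, so the residual-energy semigroup
`E(s₁+s₂) = E(s₁) then s₂` holds to interpolation tolerance everywhere.
Energies above the table span fail explicitly.

`trace_alphas()` finds every nucleus sphere intersected by the segment from
the emission point over the particle's full range: entry/exit energies
(`Ei`, `Ef`, with `Ef = 0` when the track stops inside), chord, and a
self/cross flag per crossing, sorted by entry distance with deterministic
tie-breaking. A uniform spatial hash (voxel size twice the largest nucleus
radius, with a sampling margin that guarantees no sphere on the segment is
missed) accelerates candidate lookup; `method = "brute"` runs the all-pairs
loop and produces bit-identical crossings, which the test suite asserts
against an independent pure-R oracle as well. Per track, the energies
deposited in nuclei, elsewhere inside the spheroid sphere, and beyond it sum
to the emission energy exactly.

`tally_dose()` converts deposits to specific energy with each cell's actual
nucleus mass (water density): 1 MeV in a 5.5 µm nucleus is 0.230 Gy. Per
cell it reports self and cross components, their sum Zn, and the cross-fire
fraction `Cn = z_cross/Zn` (defined as 0 when Zn = 0); per spheroid, the
absorbed dose over the spheroid water mass, counting all energy imparted
inside the 95 µm sphere including the intercellular matrix.

# Biophysical endpoints

## Survival

Two survival routes share the crossing records:

* **Cumulative lethal-function interface** (`survival_lethal_events()`):
  non-decreasing tables F_L(E), F_G(E) of local-lethal and global events
  versus kinetic energy; a crossing contributes `F(Ei) − F(Ef)` of each and
  `S = exp(−(n_L + n_G))`. This is the integration surface for externally
  computed nanodosimetric tables, which are not published and therefore not
  shipped.
* **Charlton-style mean free path** (`survival_charlton()`): each crossing
  contributes `chord/λ(LET)` lethal events with LET the finite difference
  `(Ei − Ef)/chord`; `S = exp(−Σ chord/λ)`. The shape of λ(LET) follows the
  classical parameterization — linear below 100 keV/µm, constant above
  200 keV/µm, linear bridge between — but the published fit coefficients are
  not recoverable, so the shape is fixed a priori (λ(0)/λ(100) = 3, plateau
  0.8·λ(100)) and a single scale is calibrated. The slope expresses that
  lethal events per unit path grow with ionization density; the plateau
  expresses overkill saturation. `lethal_table_from_charlton()` integrates
  the same λ along the slowing-down path into a cumulative table, tying the
  two routes together (the tests check they agree).

Nuclei that shrank during packing keep their nanotarget count, so
lethal-event counts are scaled by (nominal nucleus volume / actual nucleus
volume) — the same normalization used for cell-line transfer.

## Calibration design

The single λ scale is pinned to one published operating point: membrane
distribution, reference spheroid, A_TCP=0.9 = 0.387 mBq.
`calibrate_charlton()` simulates the configurations once at 0.387 mBq and
root-finds the scale so the mean TCP there equals 0.9 — equivalent, for a
TCP monotone in activity, to forcing the activity bisection to return 0.387,
but at a fraction of the cost since survival depends on the scale only
through `exp(−damage/scale)`. Everything else — other intracellular
distributions, lognormal fluctuations, other cell lines — is then a
prediction, which is the package's validation surface. Absolute survival
levels inherit the arbitrariness of the λ shape; predicted *ratios* and
*orderings* are the meaningful outputs.

## TCP, RBE and activity search

`tcp()` computes `Π(1 − S_i)` per irradiation configuration in log space
(`Σ log1p(−S_i)`, immune to underflow at thousands of cells) and averages
over configurations with a standard error. `rbe()` is the isoeffective
photon-to-alpha dose ratio from the linear-quadratic inversion
`RBE = (−α + √(α² − 4β ln S̄)) / (2βD)`, with the analytic `−ln S̄/(αD)`
limit at β = 0; `photon_survival()` is its exact inverse, and presets for
the 140 kV (α = 0.313, β = 0.062) and 4 MV LINAC (0.259, 0.040) references
are provided. `find_activity_for_tcp()` bisects the activity for a target
mean TCP over a fixed set of configuration seeds shared across activities
(common random numbers keep the empirical TCP(APC) curve monotone), failing
explicitly with the endpoint TCPs when the bracket does not straddle the
target. With uniform counts the TCP is a step function of activity — steps
at half-integer decay counts — so the returned activity is the step location
nearest the target; its granularity (~0.013 mBq for At-211) is well inside
the tolerances used anywhere in the package.

# Experiment drivers

`reference_config()` encodes the default irradiated system: 95 µm spheroid,
75% compaction, OVCAR-3 geometry with HSG photon coefficients, At-211,
uniform activity of 1.12 mBq (42 decays) per cell, membrane distribution, no
daughter diffusion. `run_reference()` reports mean Zn, mean Cn, spheroid
dose (and, given a survival model, mean survival, TCP and RBE) per
distribution and replicate. `run_sweep()` runs parameter grids over radius,
compaction, cell line, nuclide, distribution, APC, fluctuation model and
diffusion; every row carries a seed derived deterministically from the
master seed and the grid-point index, so any point can be re-run in
isolation, identical master seeds reproduce results bitwise, and a failing
point is recorded in an `error` column while the sweep continues. A thin
command-line front end (`inst/exec/alphasphere`) exposes `generate`,
`irradiate`, `endpoints`, `sweep` and `fixtures` over these functions with
CSV/JSON outputs and a run manifest.

# Problem sizes and numerical choices

The shipped checks run at deliberately modest sizes, chosen as the smallest
that leave the statistical assertions comfortably powered: 50 configurations
for the isolated-cell contrast, 3 configurations of the full ~2900-cell
reference spheroid for the dosimetric ratios (the Monte Carlo error on those
means is far below the assertion tolerances), and 20 configurations per
bisection evaluation for the activity searches, matching the lower end of
the 20–500 range appropriate for TCP averaging. Compaction estimates use
10⁵–2×10⁵ points (binomial SE ≈ 0.1–0.15 pp). Other defaults: relaxation
tolerance 10⁻⁹ µm with bounded iterations; activity bisection tolerance
0.002 mBq; calibration root tolerance 10⁻⁵ on log₁₀ scale; crossing ties
broken by cell id. Degenerate inputs have defined behavior: zero activity
gives S = 1, TCP = 0 and zero dose; a zero-thickness cytoplasm shell, an
energy above the range table, an emission outside the bounding sphere, an
unknown nuclide or cell line, and a non-straddling bisection bracket all
fail with explicit messages.

# What the generator emulates — and what it does not

The synthetic spheroid reproduces the *statistical* geometry that drives
multicellular dosimetry: cell density, nucleus size floor, disjoint nuclei,
and a realistic compaction profile. It does not reproduce mesh-level
features of real (or CPOP-generated) spheroids: polyhedral deformed
membranes, position-dependent cell sizes, extracellular-matrix contrast, or
necrotic cores. Consequently, quantities dominated by cross-fire and bulk
geometry (specific-energy ratios, cross-fire fractions, spheroid dose,
calibrated activity predictions) transfer well, while quantities sensitive
to membrane shape at µm scale (e.g. the exact self-dose of membrane-bound
decays in a deformed cell) carry a systematic uncertainty of order the
shrink fraction. Passing tests demonstrate internal correctness and
agreement with the published multicellular operating points, not fidelity
to any individual real spheroid.

For the isolated reference cell the geometry is exact (5.5/6.9 µm concentric
spheres), and the membrane-to-nucleus specific-energy contrast has a
closed-form check: the mean chord through the nucleus from a uniform
interior point is 3r/4 = 4.125 µm, against an expected path of ≈1.38 µm for
isotropic emission from the membrane sphere, giving a ratio of ≈3.0 at
nearly constant LET — the value the simulation reproduces. Published
mono-cellular contrasts larger than this are geometrically incompatible
with volume-uniform compartments of these radii under any local-deposition
transport, so the package reports the modeled value rather than matching
them.

# Known limitations

* No track-structure physics: nanodosimetric quantities are consumed
  through the lethal-function interface, never re-derived.
* Single-generation daughters only; no multi-alpha decay chains or
  pharmacokinetic redistribution.
* The nucleus is the only sensitive volume; no membrane/cytoplasm
  radiosensitivity, no repair kinetics or dose-rate effects.
* The λ(LET) shape is a two-parameter stand-in for unpublished tables;
  absolute survival values should not be over-interpreted.
* Uniform water everywhere: no density contrast between cells and matrix.
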