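---
title: "Models and methods of the microbrachy pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the microbrachy pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbrachy)
```

This vignette is the package's own account of the science it implements:
the physical and statistical models, the assumptions behind them, the
tunable parameters and why their defaults are what they are, and the
places where a genuine design choice had to be made.

## The treatment being modelled

Microbrachytherapy (mBT) treats a small (1–3 cm) brain tumor by
injecting a radioactive microparticle suspension directly into it, as a
series of discrete 5–8 µl *units of treatment* (UoTs), each placed at a
planned position with a stereotactic needle. The suspension carries
¹⁶⁶Ho, a beta emitter with a 26.8 h physical half-life, bound in ~470 nm
particles at 550 g/L dry matter and 28 % holmium by weight. Two physical
facts make the computational chain tractable:

1. The particles do not migrate: post-operative CT shows the deposits
   fixed at the injection sites for weeks. Dose delivery is therefore
   *physical decay in place* — no biological clearance term.
2. The beta range in soft tissue is millimetric, so each UoT irradiates
   a roughly spherical neighborhood and coverage is controlled by where
   the UoTs are placed.

The planning objective is fixed by the therapy's prescription: deliver
at least 95 % of the 100 Gy target dose to at least 95 % of the gross
tumor volume (GTV) with the fewest injections.

## Suspension and decay model

`Radionuclide()` carries the half-life (26.8 h) and the mean energy
deposited per decay. The package treats the mean energy per decay as a
**configuration constant**, default 0.665 MeV — the mean beta energy of
¹⁶⁶Ho from standard nuclear-data compilations (ICRP-107-style tables) —
not as a measured input of any particular study. The hard gammas of
¹⁶⁶Ho are excluded from the default budget: at centimeter scale nearly
all locally absorbed energy is beta energy, while the 80.6 keV and
1379 keV photons mostly escape a minipig head. Users who want a photon
contribution can raise `meanEnergyMeV`.

Decay kinetics are exact: `decayFactor(spec, t) = 2^(−t/T½)`, and the
cumulated activity (total decays over all time) is the closed form
`Ã = A₀ · T½·3600 / ln 2` MBq·s. The tests verify this against direct
quadrature of the decay curve.

`HoSuspension()` converts injected volume to particle mass
(550 g/L ⇒ 0.55 mg/µl) and activity (specific activity × decay).
The specific-activity default is 2.5 MBq/mg, the midpoint of the
2–3 MBq/mg range achievable at injection time; the interval between
activation and injection is not modelled because only the
at-injection value is specified. An 8 µl UoT at defaults is therefore
4.4 mg and 11 MBq.

## Dose engine: kernel convolution instead of Monte Carlo

Reference dosimetry for this therapy uses full Monte Carlo radiation
transport. This package deliberately replaces it with an isotropic
radial dose-point-kernel (DPK) in homogeneous water-equivalent tissue
(density 1 g/cm³, configurable). The replacement is justified by the
same assumptions the therapy itself relies on — a localized,
non-clearing beta source in soft tissue — and buys three properties a
desk-scale tool needs: determinism, speed, and testable energy
conservation.

The packaged kernel is parametric: the radial energy-deposition density
is `g(r) ∝ r² · exp(−r/r₀)` with `r₀ = 0.75` mm, truncated and
renormalized on `[0, 8.5]` mm. The 8.5 mm cutoff approximates the
maximum beta range of ¹⁶⁶Ho in soft tissue; with these constants ~90 %
of the energy is absorbed within 4 mm of a point source, the right
scale for a 1.85 MeV-endpoint beta spectrum. The constants live in a
versioned JSON fixture (`inst/extdata/ho166-beta-kernel-params.json`)
explicitly labelled as a synthetic parametric profile, and any tabulated
kernel can be substituted via a two-column CSV (`readKernelCSV()`).
Because shell fractions are exact integrals of the profile (incomplete
gamma form), the cumulative profile is invariant under re-discretization,
which the tests check by halving the shell width.

Numerical choices in the voxel resolution of the kernel:

- The kernel is resolved to integer voxel offsets by
  center-to-center distance. The **self-voxel** receives the cumulative
  energy inside the half-voxel radius; each remaining shell's energy is
  split equally among the voxel offsets falling in it.
- Shells too thin to contain any voxel offset at the current spacing
  would lose their energy, so the voxelized kernel is renormalized to
  sum to exactly 1. Consequence: for sources at least one kernel range
  from the boundary, deposited energy equals emitted energy to machine
  precision, and the 1 % conservation acceptance check passes with
  large margin.
- Convolution runs in the frequency domain after zero-padding each axis
  by the kernel's voxel radius (rounded up to an FFT-friendly length),
  so sources near the edge never wrap around. A brute-force
  pairwise-summation oracle (`bruteForceDose()`, refused above 32³
  voxels) implements the identical contract for cross-checking; the two
  agree to ~10⁻¹⁴ relative.

Each UoT is deposited as a uniform sphere of its own liquid volume
(1 µl = 1 mm³) centered at its site — the minimal geometric model
consistent with "the suspension stays where injected" — with the
containing voxel as the degenerate minimum. Activity is conserved
exactly by construction.

## The planner

The original optimization algorithm behind the therapy's planning
system is published separately and is not reproduced here; this package
implements its **objective and constraints** with a transparent greedy
heuristic:

1. Candidate sites form a regular lattice (default pitch 2 mm, snapped
   to whole voxels, anchored at the voxel center nearest the GTV
   centroid) eroded by a 1 mm safety margin: a site survives only if
   every voxel center within the margin is tumor. If erosion empties
   the set, the centroid is the sole candidate. Snapping candidates to
   voxel centers lets a single precomputed UoT dose field serve every
   site by translation, which in turn guarantees that re-simulating the
   final plan through the dose engine reproduces the planner's reported
   coverage.
2. Each iteration adds the (site, volume) pair covering the most
   not-yet-covered GTV voxels at the 95 Gy threshold, trying the
   largest allowed volume (8 µl) first since it maximizes activity per
   needle placement. Ties prefer the site nearest the centroid, then
   the lowest candidate index — full determinism, no RNG.
3. The loop stops when the covered fraction reaches 95 %
   (`feasible = TRUE`), when the injection cap (default 50, far above
   the 9–20 used clinically) is hit, or when no candidate adds coverage;
   in the latter cases the plan reports `feasible = FALSE` with the
   honest coverage achieved.

Exact minimality of the injection count is *not* claimed — greedy
maximum coverage is a heuristic — but the count behaves correctly
(non-decreasing with tumor diameter; 1 injection when the whole GTV fits
inside a single UoT's 95 Gy isodose, whose radius at defaults is about
4.2 mm). A nearest-neighbor tour over the chosen sites is recorded as
execution-order metadata, mirroring the single-needle-repositioned
technique, but does not constrain placement.

## CT quantification

The forward CT model is piecewise-constant tissue baselines
(brain 35 HU, contrast-enhanced tumor 60 HU, background −1000 HU),
a linear holmium term (default 12 HU per mg/ml), additive Gaussian
noise, and clipping to the 12-bit scanner range [−1024, 3071] HU. Only
the existence of a scanner-specific linear calibration is assumed —
linearity of CT signal in contrast concentration at fixed tube voltage
is standard; the study's acquisition energy is carried as metadata only.

Quantification inverts this: an ordinary least-squares calibration line
(`fitCalibration()`, with a synthetic known-concentration insert
generator standing in for the scanner protocol), then per voxel
`C = max(0, (HU − baseline)/slope)`. Two documented consequences of the
clipping at zero:

- within a deposit the signal is hundreds of HU, so clipping never
  activates there and recovery is unbiased;
- over large empty regions, noise-induced positive excursions survive
  clipping, so *whole-volume* totals are biased upward under noise.
  Unbiasedness holds (and is tested over 100 noise seeds) on the
  deposit support; real-scan workflows would threshold or segment
  first. Partial-volume effects beyond voxel-level linearity are a
  known, accepted limitation.

Baseline subtraction uses the pre-operative scan on the identical
lattice, which is exact by construction in synthetic runs; registration
of real scans is out of scope.

## Coverage metrics

`computeDVH()`/`evaluatePlan()` compute cumulative DVHs over the GTV and
read V₆₀Gy, V₁₀₀Gy and D95 off the exact voxel-dose multiset, never the
binned curve. D95 is defined as the largest dose d such that at least
95 % of GTV voxels receive ≥ d (an order-statistic, exact on the
multiset). 60 Gy is reported because it is the usual external-beam
prescription for this indication; 100 Gy is the therapy's own target.
Dose outside the GTV is summarized as a healthy-tissue V₁₀ context
statistic only — sparing is discussed qualitatively in this field, so
no target value is attached.

## Synthetic cohort generator

The generator defines the study conditions under which everything is
tested; its defaults are fixed once, from the published condition of the
model system:

- **Growth**: exponential, `V(t) = V₀·2^(t/T_d)`. Serial volumetry of
  untreated animals implies doubling times of roughly 2.3–5.8 days
  between treatment (day 14 after implantation) and euthanasia;
  `T_d = 3` days is the default, `V₀ = 1000` mm³ the treatment-day
  volume scale.
- **Endpoint surrogate**: untreated animals are euthanized for clinical
  signs, which cannot be modelled; the surrogate is a tumor-volume
  threshold, default 5000 mm³ (observed pre-euthanasia volumes span
  ~1700–8000 mm³). With the defaults the deterministic endpoint falls
  on day 7 post-treatment, and the published events all fell between
  days 6 and 9.
- **Heterogeneity**: per-animal log-normal jitter on `V₀`
  (sdlog 0.2) and `T_d` (sdlog 0.05), chosen so that simulated
  untreated event times concentrate in the observed 6–9 day window
  (~98 % of events over 200 seeds) while still spreading the
  treatment-day volumes severalfold. A zero dispersion is legal and
  makes the cohort deterministic; negative dispersions are an error.
- **Treated arm**: plans meeting the 95 % coverage constraint are
  censored alive at the 66-day horizon, as in the study arm where all
  treated animals reached scheduled euthanasia healthy. Under-covered
  plans regrow from the uncovered volume fraction
  `V₀·(1 − coverage)` — a deliberately crude radiobiology-free model
  whose only purpose is to make partial failure representable.

What the generator does **not** emulate: edema, hemorrhage, immune
infiltration, histology scores, scanner artifacts (beam hardening,
metal artifacts from dense deposits), real plurilobed-shape statistics,
or any dose–response radiobiology. Passing tests therefore demonstrate
the correctness of the computational chain under its stated physics,
not fidelity to any particular animal's images.

## Survival statistics

`kmEstimate()` is the product-limit estimator from first principles;
censored records leave the risk set without a step. `logrankTest()` is
the Mantel–Cox log-rank test: at each distinct event time the observed
minus hypergeometric-expected events in one group is accumulated, ties
aggregated, no continuity correction;
`χ² = (Σ(O−E))²/ΣVar` is referred to the 1-df chi-square upper tail,
computed via the complementary-error-function identity
`p = erfc(√(x/2)) = 2Φ(−√x)`. The implementation is cross-checked in
the tests against `survival::survdiff` (agreement to 10⁻⁹) and against
a full-enumeration permutation oracle.

Two reporting conventions are implemented because small-animal reports
use them:

- **Truncated means.** Group means are truncated toward zero at one
  decimal (mean(9,8,9) = 8.667 → 8.6). Medians are computed too and
  labelled separately, since for 3-animal groups mean and median
  genuinely differ.
- **Truncated p.** `pReported` truncates the raw p at the second
  decimal (0.096 → "0.09") and prints "<0.01" below the significance
  level; the raw p is always retained.

A statistical honesty note, verified by the tests: with arms of 3+3 and
5+3 animals the *exact* permutation p-values are granular — multiples
of 1/20 and 1/56 — and conservative relative to the asymptotic
chi-square tail (e.g. exact 0.30 vs asymptotic 0.096 for the 3-vs-3
comparison; 1/56 ≈ 0.018 is the smallest p exactly attainable for
5-vs-3). Asymptotic p-values below 0.01 at these sample sizes are
therefore approximations by construction; the package reports the
standard asymptotic Mantel–Cox value and exposes the exact oracle in
its test suite. For the treated-vs-other comparison reported as
significant "against the two other groups", both pairwise tests are
run (each must pass), with a pooled one-vs-rest option provided since
such statements are ambiguous.

## Pipeline, I/O and determinism

`runDemo()` chains phantom → plan → deposit → dose → post-operative CT
→ quantification → DVH → cohort → survival, writing NIfTI volumes, the
plan JSON, DVH and cohort CSVs and a report JSON whose bytes are a pure
function of (config, seed); the report carries a config fingerprint and
no timestamps. Every stochastic operation takes an explicit integer
seed and restores the caller's RNG state; the stage seeds of a run are
small fixed offsets from the master seed. Volumes round-trip through
NIfTI (via RNifti) or MetaImage (built-in minimal LOCAL-data `.mha`
reader/writer — no installed R package covers MetaImage) with exact
double-precision values and 10⁻⁶ mm geometry. Coordinates are
right-handed world mm; a voxel's position is its center; voxel indices
are 1-based in R with voxel `[1,1,1]` at the stored origin.

The report "schema" shipped in `inst/extdata/report-schema.json` is a
minimal structural contract (required fields and scalar types) enforced
by `validateReport()`; it is not a full JSON-Schema implementation,
none being available in the dependency set.

## Problem sizes

The package's own test and demonstration sizes are chosen for
interactive turnaround: planning examples use 15 mm spheres on 41³
lattices at 1 mm spacing (a few seconds), dose-oracle equivalence runs
on 16³ grids, quantification-bias checks use 100 noise seeds, and
cohort-envelope checks 200 cohort seeds. The same code runs unchanged
on finer lattices; cost scales with grid volume times the kernel's
voxel support for planning and with `N log N` for the FFT dose engine.

## Known limitations

- Homogeneous-medium dosimetry only: no CT-density heterogeneity, no
  photon build-up, no microdosimetry at the particle scale, no
  biologically effective dose.
- The greedy planner guarantees constraint satisfaction when reachable,
  not minimal injection counts; published per-animal UoT counts
  depend on a different optimizer and are not comparison targets.
- The CT model is a deliberately simple signal model; per-animal
  coverage tables from real scans are out of reach by design.
- The cohort model's treated-arm regrowth rule is a surrogate, not a
  dose–response model.
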