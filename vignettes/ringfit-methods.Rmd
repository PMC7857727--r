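---
title: "Methods: rigid-body SAXS modelling of cyclic oligomers with ringfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid-body SAXS modelling of cyclic oligomers with ringfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ringfit` analyses solution SAXS data from flat, ring-shaped multi-domain
protein oligomers of the properdin type: n compact "eye" vertices carrying
binding sites, joined by thin multi-domain arms into a C_n-like ring. This
vignette documents the models, the numerical choices and their rationale,
and what the bundled synthetic system does and does not establish.

## 1. Profiles and Guinier analysis

A profile is the triple (q, I, σ) with q = 4π sin(θ)/λ in Å⁻¹, strictly
increasing, σ > 0. Rows with σ ≤ 0 in input files are dropped rather than
refused: real beamline files occasionally contain them, and silently
keeping them would corrupt every weighted fit downstream.

Logarithmic rebinning (`rebin_log`) combines points within log-spaced q
bins by inverse-variance weighting, so the combined σ in a bin never
exceeds the best member σ. It is intended for plotting and storage
(~800 → ~180 points); model fits use the unbinned grid, because at high q
log bins become wider than the intensity oscillation period 2π/D_max of a
large particle and the bin mean is no longer the curve value.

`guinier_fit` fits ln I against q² by weighted least squares on the largest
low-q window with q·Rg ≤ 1.3, iterating the window to self-consistency in
Rg (tolerance 1e-3 Å, 50 iterations max). The 1.3 limit is the standard
compact-particle convention. The Guinier law is only the O((qRg)²) term of
an expansion; over a full 1.3 window the neglected quartic term biases Rg
of a sphere upward by 1-2%. The fit therefore retreats from the window
while its reduced χ² exceeds 2: for data whose errors are smaller than the
truncation error (e.g. noise-free oracles) the window shrinks and the bias
vanishes; for realistically noisy data the full conventional window is
kept, since nothing in the data distinguishes the quartic term. Systematic
positive residuals of the first points raise an aggregation flag.

## 2. Indirect Fourier transformation

`ift_pr` inverts I(q) = 4π ∫₀^Dmax p(r) sinc(qr) dr on 101 equally spaced
r bins with both endpoints pinned to zero, by ridge regression: the data
misfit is weighted by 1/σ², and a second-difference (curvature) penalty
with weight α stabilizes the inversion. α is chosen by generalized
cross-validation over a log grid spanning ten decades around a
dimensionally neutral unit (trace ratio of the two quadratic forms). The
101-bin histogram basis is the simplest choice that resolves every feature
the study needs (bin width ≈ Dmax/100 ≈ 2-4 Å); hard non-negativity is not
imposed — the type tolerates ripple down to −1% of max p and warns beyond —
because the constrained solve buys little for well-measured data and
complicates the linear algebra.

`scan_dmax` selects D_max by re-running the IFT over a candidate grid. Two
diagnostics define the selection: (i) the χ² plateau — extra D_max freedom
always absorbs a little noise, so the raw χ² minimum systematically
overshoots; a candidate counts as on-plateau within
max(0.05, 2·√(2/n)·χ²_min) of the minimum, the second term being twice the
sampling spread of a reduced χ² with n points; (ii) a clean tail — a D_max
below the true support forces the distance mass against the pinned
endpoint, producing a pile-up or negative dip in the last bins, so the
last three interior bins must stay below 5% of max p in magnitude. The
smallest on-plateau candidate with a clean tail is selected. On sphere
oracles this lands on 2R within one grid step; on noisy ring models it
overshoots the true maximum extent by a few percent, which is the familiar
conservative behavior of regularized IFT.

`find_peaks` reports local maxima with prominence ≥ 2% of max p (positions
refined by three-point quadratic interpolation) and, on request,
shoulders as second-derivative zero crossings without a first-derivative
sign change.

## 3. Debye intensities and fitting

Bead models are point scatterers with per-bead weights; the Debye sum
I(q) = Σᵢⱼ wᵢwⱼ sinc(q rᵢⱼ) is computed exactly (compiled double sum) or
via a pair-distance histogram with linear (triangular-kernel) mass
splitting between neighboring grid points at 0.25 Å. The linear binning
keeps the approximate intensity a continuous function of coordinates —
essential for the local optimizers in refinement — with relative error
below 1e-3 over the q range used here. No solvent-excluded-volume or
hydration-shell term is included: all downstream conclusions rest on
geometry (distances, tilts), not absolute contrast, and every comparison
to data carries a free scale factor plus an optional additive constant
(absorbing small buffer-subtraction offsets). Reduced χ² divides by
n − k with k the number of fitted nuisance parameters (2 with the
constant); the BME module instead divides by n, the common convention
there, and both choices are recorded where they apply.

## 4. Restrained rigid-body refinement

An assembly is one protomer's rigid bodies (local coordinates plus a
proper rotation and translation each) and a symmetry order n; realization
applies the placements and then C_n about z, the convention in which
starting models are pre-oriented. Restraints are flat-bottom quadratics on
anchor-anchor distances: zero within the tolerance, k(|d−t|−tol)² beyond.
For the synthetic system, targets are the designed connectivity distances
(eye-to-arm and arm-to-arm along the ring, closing onto the next
protomer's eye) with a 10% flat bottom and k = 10; a soft-sphere clash
term k(3.8 − d)² for inter-body bead pairs below 3.8 Å (the Cα-Cα virtual
bond length) discourages interpenetration.

The objective is reduced χ² + restraint energy + clash energy (unit
weights; all three share the χ² scale). Optimization proceeds in four
stages, each motivated by a failure mode of the previous one:

1. **Simulated annealing** over single-body rotation/translation moves
   (σ = 5 Å, 10°, shrinking with √(T/T₀); T₀ set so that about half of
   initial uphill probe moves would be accepted). Cooling is geometric per
   100 moves with the factor derived from the move budget so that the
   final temperature is 1e-7 of T₀ regardless of budget — a fixed cooling
   factor barely cools a short run on the very steep χ² landscapes these
   low-noise data produce.
2. **Per-body Nelder–Mead polish** (6 DOF at a time, sweeps with early
   stopping) cleans up the annealed state cheaply.
3. **Basin hops**: each body in turn is kicked by a random rotation
   (σ = 25°), re-polished locally, and kept only on improvement — this
   escapes the shallow single-body orientation minima (eye tilt) that the
   data constrain only weakly.
4. **Joint quasi-Newton refinement** (BFGS with numerical gradients over
   all bodies' stacked 6-DOF parameters) removes the zigzag limit of
   coordinate descent; with it, every run that found the right basin
   converges to the same χ² floor, which is what makes the outlier rule
   (discard runs with χ² > 2× the best) and the clustering meaningful.

Optimization may evaluate the objective on every `fit_stride`-th point of
the profile: SAXS grids oversample the Shannon spacing π/D_max severalfold,
so stride 2-3 loses no information; reported χ² always uses the full
fitted range (default q ≤ 0.27 Å⁻¹). The objective is invariant under
global rotation about z and translation along z; this degeneracy is left
in place (it does not affect any reported statistic, all of which are
isometry-invariant).

`run_batch` draws randomized starts (uniform body rotations ≤ 60°,
translations ≤ 30 Å, redrawing clashing starts), refines each with its own
seed, discards χ² outliers, clusters the rest by RMSD between their
anchor-anchor internal distance vectors (single linkage, 15 Å cutoff), and
reports the largest cluster's medoid (ties to lower χ²).

## 5. Shape metrics and the α statistic

Principal axes come from the unweighted gyration tensor about the
centroid (the study's molecules are chemically homogeneous at bead
resolution; mass weighting is not applied and this is recorded here). For
flat rings the smallest axis is the ring normal. Each axis sign is
canonicalized (largest-magnitude component positive); if that leaves a
left-handed triple the largest axis is negated — the two conventions in
the type's contract (per-axis canonicalization, right-handedness) cannot
always hold simultaneously, and α depends only on the smallest axis, so
the adjustment is inert. A smallest eigenvalue within 1% of the middle one
triggers a degeneracy warning: α is ill-defined for non-flat models.

α is the angle between the per-protomer anchor vector (from the Ser345
stand-in to the Ala402 stand-in, the vector lying in the eye plane) and
the smallest principal axis, averaged over protomers; if the mean is
below 90° the axis is flipped and the angles recomputed, so the mean lies
in [90°, 180°]. The flip resolves a real degeneracy: for a planar ring,
mirroring the eyes through the ring plane leaves the scattering unchanged
while sending α to 180° − α, so only the flipped representative is
identifiable — 180° means all binding sites point the same way along the
ring normal, 90° means they lie in the ring plane.

## 6. BME ensemble reweighting

Given M calculated member curves and a profile, BME minimizes
χ²(w)/2 − θ S_rel(w) over the weight simplex, S_rel = −Σ wᵢ ln(wᵢ/wᵢ⁰).
The solution has the exponential form wᵢ ∝ wᵢ⁰ exp(−Σ_q λ_q Iᵢ(q)) and is
found in the convex dual. Numerical choices that matter:

* the dual is parametrized in θ-scaled multipliers so its conditioning is
  uniform across the whole θ range;
* a free scale (optionally + constant) for the ensemble average is refit
  between dual solves (calculated and experimental curves never share an
  absolute scale);
* at small θ the dual is nearly flat — and unbounded along directions the
  ensemble cannot fit — so every dual evaluation tracks the primal-best
  weights visited, and that best iterate is returned (flagged when the
  gradient criterion, norm < 1e-6, was not met);
* `scan_theta` warm-starts each θ from the previous solution, which keeps
  the L-curve numerically monotone to well under 1% — the exact solution
  family is monotone, and residual wiggle at the noise floor is solver
  tolerance, which is why the tests assert monotonicity with a small
  tolerance rather than exactly;
* the elbow is the maximum discrete curvature of the (φ_eff, χ²) polyline.

## 7. The synthetic system — what it emulates and what it does not

`make_oligomer` builds one protomer from rigid bodies: an eye — a prolate
ellipsoid of semi-axes (20, 14, 14) Å at `eye_extent` 40, long axis along
the binding-site vector, filled with a deterministic Halton sequence and
completed by surface cap/rim beads so the realized body reaches its
designed extent — plus three 9 Å arm sub-clusters on the arc toward the
next vertex at quarter fractions; then C_n about z. The binding-site
vector is tilted `alpha_true` degrees from +z in the radial plane, and the
arm attachment points sit on the eye's tangential axis, so the tilt is a
genuine soft mode constrained by scattering anisotropy, not by the
restraints — which is exactly the identifiability question the refinement
recovery experiment probes. Geometry is bit-deterministic: only profile
noise consumes the RNG stream.

Presets `fp2`/`fp3`/`fp4` fix (n, eye separation, tilt) =
(2, 165 Å, 150°), (3, 180 Å, 128°), (4, 195 Å, 109°) — the dimer, trimer
and tetramer study conditions. Default bead counts are roughly residue
level (160 per eye, 55 per arm cluster); the tests and the acceptance
script run the refinement recovery at reduced counts (24 and 6), which
preserves every length scale the analysis measures while keeping a 30-run
experiment within minutes — the problem sizes used are 10 runs × 3
presets, 3000 annealing moves, stride-3 objective.

At residue-level bead counts the three arm clusters together carry about as
much mass as the eye, and the long-range region of p(r) then mixes arm-arm
and eye-eye distances; the pipeline's quick eye-separation estimate (the
tallest peak beyond 100 Å) is therefore meaningful for vertex-dominated
models (reduced arm mass), while for full models the eye-eye repeat is the
long-range peak nearest the refined eye separation. The refinement-based
estimate does not share this caveat.

The noise model is σ(q) = ν I(0)(0.001 + 0.02 (q/q_max)²) + 0.01 ν I(q):
a small absolute floor growing quadratically with q plus a 1%-of-ν
relative term, mimicking the q-dependence of beamline statistics. At
ν = 0 this formula would return zero, violating the σ > 0 invariant, so σ
is then evaluated at a reference level of 0.01 and no noise is added.

What passing the synthetic closure does **not** show about real data: the
generator has no inter-domain flexibility (real FP2 is visibly curved and
possibly non-symmetric), no glycan contrast, no solvent effects, no
inter-frame correlation of SEC-SAXS, and its eyes are smooth ellipsoids
rather than structured domains — so real-data χ² values and the absolute α
calibration will differ even when the method is sound. The recovery
experiment establishes identifiability of (eye separation, tilt) under the
stated noise, not beamline realism.

## 8. Known limitations

* No CRYSOL-style hydration shell: absolute χ² against deposited
  synchrotron data is expected to differ from values obtained with
  atomic-level calculators.
* D_max selection inherits the smoothness prior's conservatism (few
  percent overshoot on noisy data).
* C₁ (asymmetric) refinement is supported by building all protomers'
  bodies explicitly, but the package's batch tooling is tuned for the
  C_n case; flexible-linker (self-avoiding dummy residue) modelling is
  out of scope.
* The α statistic assumes a flat assembly; it warns, but still answers,
  when the gyration tensor's two smallest eigenvalues are nearly
  degenerate.
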