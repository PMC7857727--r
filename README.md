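# ringfit

Solution small-angle X-ray scattering (SAXS) analysis for ring-shaped
multi-domain protein oligomers.

The motivating system is properdin (FP), the positive regulator of the
complement alternative pathway. FP circulates as head-to-tail dimers,
trimers and tetramers (FP2/FP3/FP4) whose vertices — compact ~40 Å "eyes"
formed by the TB domain and TSRs 1/4/5/6 — carry the convertase (C3b)
binding sites, joined by thin TSR2–TSR3 connecting arms. Two questions drive
the analysis: how extended and rigid are these rings in solution, and in
which direction do the n binding sites point? `ringfit` implements the full
chain of computation needed to answer them from 1D SAXS profiles, and a
synthetic oligomer generator so that every stage can be validated against a
known ground truth without any external data.

## What is inside

* **Profile handling** — 3-column ASCII I/O, validation, logarithmic
  rebinning with inverse-variance statistics, iterative Guinier analysis
  (`ln I ≈ ln I₀ − q²Rg²/3` on the self-consistent window `q·Rg ≤ 1.3`).
* **Pair distance distribution** — regularized indirect Fourier transform
  `I(q) = 4π ∫ p(r) sinc(qr) dr` on a histogram basis with second-derivative
  (Tikhonov) smoothing, generalized cross-validation for the penalty weight,
  automatic D_max selection by χ² plateau plus tail diagnostics, and
  peak/shoulder detection.
* **Model intensities** — the Debye formula
  `I(q) = Σᵢⱼ wᵢwⱼ sin(qrᵢⱼ)/(qrᵢⱼ)` for coarse-grained bead models, exact
  or histogram-accelerated (documented error < 1e-3), with free scale +
  constant fitting and reduced χ².
* **Rigid-body refinement** — restrained simulated annealing of body
  placements under C_n symmetry about z (flat-bottom distance restraints,
  soft-sphere clash term), followed by per-body Nelder–Mead polish, basin
  hops, and a joint quasi-Newton refinement; batch mode with randomized
  starts, single-linkage clustering on anchor-distance RMSD and a medoid
  representative.
* **Shape metrics** — gyration-tensor principal axes; the binding-site
  orientation statistic α (angle between the per-protomer eye vector and the
  smallest principal axis, averaged and flipped into [90°, 180°]); exact
  model D_max; direct model p(r).
* **Ensemble reweighting** — Bayesian maximum entropy (BME): minimize
  `χ²(w)/2 − θ·S_rel(w)` over ensemble weights in the convex dual, with a
  free scale refit and an L-curve θ scan with elbow detection.
* **Synthetic data** — deterministic "eye + arm" cyclic oligomer builder
  (quasi-random ellipsoid fills, named Ser345/Ala402-like anchor beads,
  controllable eye separation and tilt) plus a beamline-like noise model.

## Worked example

```r
library(ringfit)

# a synthetic trimer: eye separation 180 A, eye tilt 128 degrees
# (reduced bead counts -- the same system the test suite refines)
truth <- make_oligomer(synthetic_preset("fp3", eye_beads = 24,
                                        arm_cluster_beads = 6))
prof  <- simulate_profile(truth$model, noise_level = 0.01, seed = 7)

guinier_fit(prof)
#> <guinier_result> Rg = 105.73 A, I0 = 3.58e+04, 5 pts (q 0.005..0.01093, qRg <= 1.30)

sc <- scan_dmax(prof, seq(160, 470, length.out = 16))
pr <- attr(sc, "pr")
pr
#> <pair_distribution> dmax = 242.7 A, Rg = 104.58 A, I0 = 3.572e+04 (101 r bins)

subset(find_peaks(pr), position > 100)
#>   position   height kind
#> 3 104.7462 15.74184 peak
#> 4 148.1566 14.00133 peak
#> 5 185.2361 32.60795 peak
```

The tallest long-range p(r) peak (185 Å) sits close to the designed 180 Å
eye-eye separation; D_max (242.7 Å) lands a few percent above the true
maximum extent (232.6 Å for this model), the usual conservative behavior
of regularized IFT. Refinement then recovers the full geometry from
scattering alone:

```r
batch <- run_batch(truth$assembly, synthetic_restraints(truth), prof,
                   refine_config(n_moves = 3000, fit_stride = 3),
                   n_runs = 10, seed = 11)
rep_model <- batch$runs[[batch$representative]]$model
eye_separation(rep_model)            # 180.4  (truth 180)
alpha_angle(rep_model)$mean_alpha    # 126.7  (truth 128)
```

(A 10-run batch at these bead counts takes a few minutes on one CPU.)

The numbered scripts under `analysis/` run the whole study end to end —
simulation, model-free analysis, refinement batches, orientation statistics
and BME reweighting — writing tables under `results/`.

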