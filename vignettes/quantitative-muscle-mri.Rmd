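---
title: "Multi-parametric quantitative muscle MRI: models, phantom, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric quantitative muscle MRI: models, phantom, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Muscular dystrophies progressively replace contractile muscle tissue with
fat. Quantitative MRI tracks this process with a panel of per-muscle
biomarkers: the fat fraction (FF) and contractile cross-sectional area
(cCSA) measure irreversible fat replacement, while water T2, water T1,
diffusion-tensor metrics and intramuscular pH are sensitive to disease
activity — edema, inflammation, membrane damage — before fat appears.
`muscleqmri` implements the full processing chain for such a panel, from raw
multi-echo image stacks to the long-format muscle-record table used for
longitudinal statistics, together with a synthetic lower-limb phantom that
gives every stage a known ground truth.

This vignette records the models the package fits, the defaults it ships
with, and the reasoning behind the numerically delicate choices. Nothing
here reports an empirical result that the test suite and
`scripts/acceptance.R` do not themselves recompute.

## The phantom

`phantom_config()` describes a voxel grid (default 64 x 64 x 5 at
1 x 1 x 5 mm) holding eight elliptical-cylinder muscles, four per side,
mirrored left/right. Elliptical cylinders are the simplest shape that keeps
every muscle comfortably above the 50-voxel retention rule at the default
grid; partial-volume effects at muscle borders and realistic anatomy are
deliberately out of scope, so a passing recovery suite says "the estimator
inverts its forward model under noise", not "the estimator is robust to
segmentation error". Per-muscle truth spans the pathological range: FF 2-60
%, water T2 28-45 ms, water T1 1000-1400 ms, mean diffusivity 1.4-1.8
um^2/ms, fractional anisotropy 0.21-0.32, pH 7.00-7.15. Two smooth in-plane
polynomial fields supply the artifacts every estimator must survive: a
multiplicative transmit field B1+ spanning 70-130 % of nominal, and an
off-resonance field psi spanning +/-50 Hz.

Noise is Rician by construction: i.i.d. complex Gaussian noise of standard
deviation `sigma` is added to both channels before any magnitude is taken.
`sigma` is expressed in units of the unit muscle signal, so `sigma = 1/40`
gives image SNR 40 in a modality whose per-image signal is about 1 (Dixon,
spin-echo, diffusion b = 0). The fingerprint train's per-image signal is the
recursion amplitude, roughly 0.32 on average, so the SNR-40 condition for
that series uses `sigma = mean(|signal|)/40`; SNR is a property of the
acquired images, and treating it otherwise would hold the fingerprint data
to a several-fold harsher condition than the other modalities.

Everything is seeded: the same `(config, seed)` reproduces every series bit
for bit, and each modality draws from its own derived seed stream so that
adding one series never perturbs another.

## Dixon fat-water separation

Three gradient echoes at TE = 2.75/3.95/5.15 ms are modelled per voxel as

    S(TE) = (W + F exp(i 2 pi f_fat TE)) exp(i 2 pi psi TE) exp(-TE/T2*),

a single-peak fat spectrum at -3.4 ppm and a single shared T2* decay. For
fixed `(psi, T2*)` the nonnegative amplitudes solve a 2 x 2 least-squares
system, so fitting reduces to a 2-D search. Two numerical points matter:

* **Fat-water swaps.** The three-echo misfit is bimodal in `psi`; the wrong
  mode swaps water and fat. The package resolves this spatially: a coarse
  `psi` grid (step 10 Hz over the unambiguous +/-1/(2 dTE) window) is
  followed by iterated-conditional-modes sweeps that penalize deviation from
  a signal-weighted Gaussian smooth of the current field map (4 sweeps,
  penalty 3e-5 per unit relative misfit per Hz^2, smoothing SD 3 voxels).
  On any smooth field this drives the swap fraction to zero.
* **Exactness at the optimum.** Grid-plus-parabola estimates leave
  0.1-0.2 FF points of residual error, which matters when a pure-water
  voxel must come back as FF = 0 to within 1e-6. The final stage therefore
  runs
  alternating shrinking-step parabolic line searches in `psi` and log T2*
  (18 rounds, each accepted only if the residual decreases), which reaches
  the exact solution on noiseless data and costs only elementwise work.

T2* is bounded to [5, 100] ms: with three echoes spanning 2.4 ms the decay
is barely identifiable and the bound keeps the search stable. Zero-signal
voxels are masked, never fitted, and never contribute zeros to muscle means.

## Tri-exponential water T2

Seventeen spin echoes at n x 9.5 ms are fitted to one free water exponential
plus a fat term with two fixed components (T2 180/50 ms, weights 0.7/0.3,
shared between generator and fitter). Only `(A_w, T2w, A_f)` are free:
seventeen magnitude points cannot support per-voxel fat T2 estimation, and
the two-component fat shape is a configurable constant of the model. The
T2w profile is searched on a dense 0.5 ms grid with parabolic refinement;
the refined point is kept only if it lowers the residual, so an exact
on-grid optimum is returned unperturbed.

Magnitude data have a Rician noise floor, and at late echoes the floor is
absorbed by the slow fat component, biasing T2w downward in lean muscle. When
a noise estimate is available — by default from the background voxels outside
the fit mask, whose Rayleigh mean is `sigma sqrt(pi/2)` — the data are
floor-corrected in quadrature (`sqrt(max(M^2 - 2 sigma^2, 0))`) before
fitting. This first-moment correction is adequate above per-voxel SNR of a
few; no full Rician likelihood is fitted, a documented limitation.

The exclusion rules are strict inequalities exactly as stated: water T2
below 15 ms or above 70 ms, B1+ below 80 % or above 120 % of the prescribed
flip angle; values on the boundary are retained. The B1 map is accepted in
fraction-of-nominal or percent units. Note that the generator applies B1
only as an amplitude weighting; real refocusing-pulse errors also bias T2
(an EPG-level effect that is out of scope), so the B1 gate is exercised as
bookkeeping, not as physics.

## Water T1 by fingerprint matching

The fingerprint forward model is an inversion-prepared, perfectly spoiled
gradient-echo recursion over the schedule's flip angles and TRs, with each
voxel a two-compartment sum: a water pool at the voxel's T1 and a fat pool
at T1 = 371 ms, mixed by the fat fraction, both scaled by the local B1+.
The dictionary holds one unit-normalized fingerprint per node of the
(T1w 600-2000 ms step 25, FF 0-100 % step 2.5, B1 0.7-1.3 step 0.05) grid;
matching maximizes the magnitude of the complex matched-filter inner
product by exhaustive search, with exact ties broken deterministically
towards the lowest T1, then the lowest FF (node rows are pre-sorted so a
first-match argmax implements this).

Two design points were genuinely open and were settled as follows:

* **Fat chemical-shift phase.** A fat pool that differs from water only by
  T1 leaves (T1, FF, B1) nearly collinear under normalized matching — a
  mixture of exponentials can imitate any intermediate T1. The model
  therefore includes the constant phase `exp(i 2 pi f_fat TE)` the fat
  resonance accrues at the echo time, and the default TE of 1.75 ms places
  fat near quadrature with water at 3 T, making the FF axis identifiable
  the same way Dixon imaging does.
* **Schedule.** A smooth single-lobe constant-TR ramp encodes T1 poorly at
  realistic SNR. The default 400-pulse train interleaves 25-pulse segments
  at alternating flip levels (10-80 degrees) — low-flip segments read T1
  recovery almost independently of B1, high-flip segments pin B1 — with a
  sawtooth TR sweep from 12 to 900 ms that gives saturation-recovery
  contrast and large signal excursions. Both pattern and grid are plain
  function arguments; nothing downstream assumes this particular train.

Voxels with Dixon FF above 60 % are excluded from T1 analysis (strict). A
"corrupted-data" reason code exists in the ledger vocabulary, but no
automatic detector is implemented — no defensible criterion is available.

## Diffusion: DOFS, noise, tensors

The diffusion chain processes, per mixing time, one b = 0 plus six
directions at b = 400 s/mm^2, each acquired at six readout shifts
(1.1-12.2 ms). Across shifts the voxel signal is

    S(t_s) = (W + F exp(i 2 pi f_olef t_s)) exp(i (phi0 + 2 pi psi t_s)),

where `F` is the olefinic fat (+0.6 ppm from water) that SPAIR leaves
behind. For fixed `psi` the complex amplitudes are linear; `psi` is found by
a 5 Hz grid plus shrinking parabolic refinement. The model is exactly
swap-degenerate — `(W, F, psi)` and `(F, W, psi + f_olef)` fit identically —
and the physical prior that olefinic fat is the minor component resolves
it: candidate solutions with `F > W` are rejected during the search (with a
fallback to the unconstrained solution if nothing survives). The supplement
describing the study's own adjusted decomposition is not public; this
implementation is a least-squares formulation matching the printed inputs
and outputs, flagged as an approximation.

Noise is estimated from local 5 x 5 patches of the b = 0 volumes by
principal component analysis with a Marchenko-Pastur-style split of the
eigenvalue spectrum; SNR is mean b0 signal over sigma, capped at 1e6 so
noise-free input is "above any threshold" rather than infinite. Denoising
itself is estimation-only: sigma feeds the SNR gate, the signal is not
altered.

Tensor fitting takes per-volume b-matrices (a helper builds them from
b-values and directions, optionally with idealized imaging-gradient cross
terms), initializes from the log-linear solve and polishes with
Gauss-Newton on `S0 exp(-b:D)`. With seven volumes and seven parameters the
fit is exactly determined and the two stages agree; the nonlinear stage
matters when more volumes are supplied. Negative eigenvalues are clamped to
zero and flagged. Exclusions are strict as printed: voxel SNR below 15,
olefinic FF above 10 %, muscle FF above 50 %, muscles under 50 voxels;
muscle-level rules dominate voxel-level ones in the ledger.

The diffusion time is the mixing time plus the fixed 16.3 ms implied by the
sequence timing (100 -> 116.3 ms and so on). The quantitative interpretation
of diffusion-time dependence (random permeable barrier modelling) is out of
scope.

## Intramuscular pH

The carnosine imidazole C2H proton shifts with pH along a
Henderson-Hasselbalch titration curve between a protonated limit
`delta_acid` and a deprotonated limit `delta_base`:

    pH = pKa + log10((delta_acid - delta) / (delta - delta_base)).

The defaults (pKa 6.87, limits 8.52/7.63 ppm, water reference 4.70 ppm) are
literature-derived configuration, not values asserted by this package; every
test uses only midpoint, monotonicity and round-trip properties, never the
constants as ground truth. Peaks are located as window maxima (water
4.2-5.2 ppm, C2H 7.5-8.7 ppm) with three-point parabolic refinement for
sub-bin accuracy; the axis is re-referenced so water sits at exactly
4.70 ppm. If no C2H point rises above twice the noise SD (taken from the
peak-free 5.8-7.2 ppm window), pH is reported unavailable rather than
guessed. Muscles with FF above 30 % (strict) are omitted entirely — at that
fat load the carnosine SNR is inadequate in practice.

## ROI aggregation and statistics

`aggregate_muscle()` averages valid voxels per muscle, records the count,
and excludes muscles under 50 voxels (a muscle at exactly 50 is retained).
Global and group averages are pixel-weighted
(`sum(mean_i n_i)/sum(n_i)`), and bilateral merging uses the same weights —
the study text says only "averaged", and voxel-count weighting is the choice
consistent with the global averages; it equals pooled-voxel averaging. The
standardized response mean is `mean(delta)/sd(delta)` with the sample
(n - 1) SD. Spearman correlations use mid-rank ties with the conventional
qualitative bands (cut points 0.2/0.4/0.6/0.8); paired and unpaired rank
comparisons are thin wrappers around the exact Wilcoxon signed-rank and
Mann-Whitney tests, checked in the suite against exhaustive enumeration
oracles for n <= 8. Linear mixed models are deliberately not implemented:
the package exports the tidy long-format table (plus a JSON exclusion
ledger) for external fitting.

Every exclusion path — voxel-level reason codes in the maps, muscle-level
flags in the records — flows into an append-only ledger whose counts must
reconcile (`retained + sum(per reason) = total`); the suite asserts this on
every pipeline run.

## Problem sizes and limitations

The recovery suites run on the default 64 x 64 x 5 grid (about 10^4 muscle
voxels) for Dixon and T2, and on single- or three-slice variants of the
same grid for fingerprinting and diffusion, where exhaustive dictionary
matching at ~30k nodes and the shift-wise decomposition dominate the cost;
these sizes give stable medians while keeping a full run of suite plus
acceptance script within a few minutes on one core. Known limitations, all
deliberate: no EPG/stimulated-echo physics (B1 affects amplitude only in
the spin-echo generator), no multi-peak fat spectrum in the Dixon stage, no
partial-volume or anatomy realism in the phantom, first-moment-only Rician
handling, and no automatic corrupted-data detector for fingerprint series.
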