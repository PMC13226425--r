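---
title: "Models and methods behind igdyn"
author: "igdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind igdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

igdyn analyses the backbone dynamics and multi-conformer structure of small
beta-sandwich (IgI-fold) protein domains from solution-NMR data: per-residue
15N relaxation rates, a global rotational-diffusion description, Lipari-Szabo
model-free parameters with a two-tier model-selection scheme, and the
restraint-compatibility analysis used to resolve alternative loop conformers
in a calculated ensemble. This vignette explains the models, the conventions
and the numerical choices, and states what the synthetic-data generators do
and do not emulate.

## Spin physics

An amide 15N spin relaxes through the dipolar coupling to its attached
proton and through its chemical-shift anisotropy (CSA). With the spectral
density J(w) (units s/rad, 2/5 normalization folded in), the standard rate
expressions are

    R1  = (d^2/4) [J(wH-wN) + 3 J(wN) + 6 J(wH+wN)] + c^2 J(wN)
    R2  = (d^2/8) [4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)]
          + (c^2/6) [4 J(0) + 3 J(wN)] + Rex
    NOE = 1 + (d^2/4) (gH/gN) (1/R1) [6 J(wH+wN) - J(wH-wN)]

with d = (mu0/4pi) hbar gH gN / rNH^3 and c = wN * dSigma / sqrt(3).
`field_context()` holds the constants. The defaults are the values in common
use for backbone amides — rNH = 1.02 A, 15N CSA = -160 ppm, gH/gN = -9.8656,
1H frequency 800.13 MHz — and all are overridable, because recovered motional
parameters shift by a few percent under alternative conventions (rNH = 1.04 A
or CSA = -172 ppm are also common). No single "true" pair exists; the choice
is therefore exposed rather than hidden.

The five motional models share the Lorentzian-sum spectral density

    J(w) = (2/5) [ S2 tau_c / (1 + (w tau_c)^2)  +  A tau' / (1 + (w tau')^2) ]

with A = 0 (models 1, 2: S2 only, optionally + Rex), A = 1 - S2 and
1/tau' = 1/tau_c + 1/tau_e (models 3, 4: explicit internal time, optionally
+ Rex), and A = S2f - S2 with 1/tau' = 1/tau_c + 1/tau_i (model 5: extended
two-timescale form, with the fast internal motion taken as infinitely fast so
only S2 and S2f appear as amplitudes). Model 5 is parameterized internally as
(S2f, S2s, tau_i) with S2 = S2f * S2s, which enforces S2 <= S2f by
construction. Units are seconds and rad/s internally; interfaces use ns for
times and s^-1 for rates.

## Decay fitting and heteronuclear NOE

Peak-volume series are fitted as V(t) = V0 exp(-R t) by Levenberg-Marquardt
in the nonlinear form (not log-linearized), matching the behaviour of the
curve fitting in standard NMR analysis software and weighting noisy
long-delay points sensibly; V0 starts from the first point and R from a
two-point log estimate. The reported uncertainty is the standard error from
the fit covariance — the convention when duplicate delays are not recorded.
Residues with fewer than three usable points, non-convergent fits or a
non-positive fitted rate are emitted as missing, never imputed, and never
abort a batch. The heteronuclear NOE is the saturated/reference volume ratio
with the replicate-difference error |NOE - NOE_repeat|, the standard choice
when the experiment is repeated exactly once.

## Rotational diffusion

For a rigid N-H vector the R2/R1 ratio depends only on overall tumbling, so
the ratio of residues without fast internal motion reports on the global
diffusion tensor. Residues enter the fit when their heteronuclear NOE
exceeds 0.6 (the customary cutoff, exposed as a flag); exchange-broadened
residues inflate R2 and would bias tau_c upward, which is why apparent
per-residue tau values are also useful diagnostics (`residue_tauc()` inverts
the rigid ratio curve, bracketed in 0.1-50 ns where it is strictly
increasing).

The spherical model is a one-parameter chi-square fit over ratios with
first-order error propagation of the ratio uncertainties; sigma(tau_c) comes
from the curvature of the chi-square at the minimum. The axially symmetric
model has four parameters (D_iso, D_par/D_perp, two axis angles). The search
uses the quadric approximation — the apparent local diffusion coefficient
D_i = 1/(6 tau_c,i) varies with N-H orientation n_i as n_i' Q n_i with
Q = (Tr(D) I - D)/2, linear in the tensor for a fixed axis, hence solvable by
weighted least squares on a 13x13 axis grid — and the winner is refined
against, and the final chi-square reported from, the full three-exponential
axially symmetric spectral density (correlation times 1/(6 Dperp),
1/(5 Dperp + Dpar), 1/(2 Dperp + 4 Dpar)). Sphere and axial fits are
compared with F = [(chi2_sph - chi2_ax)/3] / [chi2_ax/(n-4)] and the F(3,
n-4) distribution.

Inertia tensors are computed over heavy atoms with element masses (hydrogens
excluded, the PDBinertia-style convention). `inertia_axes()` reports the
relative principal moments normalized to the largest (a rod reads
1.00:1.00:0.00, a sphere 1.00:1.00:1.00) plus equivalent uniform-ellipsoid
semi-axis ratios from a^2 proportional to (Ib + Ic - Ia), cyclic, as a
separate field — the two conventions are easy to conflate and published
"principal axes" figures are usually the former.

## Model-free fitting and the two-tier selection scheme

Each residue contributes three observables (R1, R2, NOE) at a fixed global
tau_c. Fits minimize chi2 = sum((obs - calc)^2 / sigma_obs^2) with bounded
parameters (S2, S2f in [0,1]; tau_e, tau_i in [0, 10 ns]; Rex in [0, 50
s^-1]) and a multi-start grid per model to avoid local minima; internal free
parameters carry times in ns so all coordinates share a comparable scale for
the bounded quasi-Newton steps.

Degree-of-freedom bookkeeping, stated explicitly because it is easy to get
wrong with only three observables: model 1 leaves 2 residual degrees of
freedom, models 2/3 leave 1, and models 4/5 leave 0. The nested F-test for
1 -> 2 and 1 -> 3 therefore has (1, 1) degrees of freedom:
F = (chi2_1 - chi2_c) / chi2_c, p from F(1,1).

Selection proceeds in two tiers:

1. Model 1 is the baseline. Model 2 or 3 displaces it only when the F-test
   gives p < 0.05; when both pass, the lower chi-square wins, ties going to
   model 2 (fewer assumptions about the internal timescale — a documented,
   deterministic tie-break). If the model-1 chi-square is already at
   numerical zero (< 1e-6), the F-tests are skipped: a finite F cannot
   justify extra parameters on an effectively perfect fit, and the statistic
   on two numerically-zero values is meaningless.
2. A model is *satisfactory* when its chi-square is below its Monte-Carlo
   critical chi-square: `critical_chi2()` simulates `n_sim` synthetic
   (R1, R2, NOE) triples at the best-fit parameters with Gaussian noise at
   the experimental sigmas, refits the same model (starting from the best
   fit), and takes the empirical nearest-rank quantile at the confidence
   level (default 0.95, `n_sim` default 500). For a 1-parameter model with
   small noise this distribution approaches chi-square with 2 degrees of
   freedom, which the tests verify. Models 4 and 5 — zero residual degrees
   of freedom, so no F-statistic is possible — are considered only when all
   of models 1-3 fail their critical values, and accepted only when their
   own chi-square beats their critical value (lower chi-square wins, tie to
   model 4).

When the F-chosen candidate fails its critical value but some simple model
would pass its own, the candidate is returned flagged unsatisfactory rather
than silently swapped: the F-test gates entry into models 2/3, and a complex
model that did not earn significance stays unavailable regardless of its
critical value. If nothing is satisfactory, the best-chi-square fit is
returned flagged, with the whole decision path recorded per residue.

Parameter uncertainties are the standard deviations of the Monte-Carlo refit
distribution. Randomness is controlled by one master seed from which each
residue derives a substream keyed on residue_id and model id, so batch
results are independent of processing order; every simulation restores the
caller's RNG state.

## Ensemble geometry

* **Superposition** is the Kabsch algorithm (SVD of the centred covariance
  with the determinant sign correction, so the rotation is always proper).
  Collinear or under-determined selections are errors.
* **Per-residue RMSD** performs one global superposition on the
  ordered-backbone fit region, then reports per-residue values — between the
  representative models of two ensembles, or as the mean RMSD of models 2..M
  to model 1 for the spread of a single ensemble. "Best structure" is model
  1 of a deposited ensemble throughout (the PDB convention for the NMR
  representative); model numbering is 1-based everywhere.
* **Dihedrals** use the IUPAC sign convention (cis = 0, trans = 180;
  phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1)); angles are undefined across
  chain breaks (peptide C-N > 2.5 A) and at termini. Circular differences
  are reported in [0, 180], invariant under 360-degree shifts.
* **Restraints**: selections with a trailing `#` expand to the proton group
  sharing the stem (methyls, methylenes, equivalent aromatic pairs, standard
  IUPAC/XPLOR naming); effective distances are r^-6 sum-averaged,
  d_eff = (sum d^-6)^(-1/6), the ARIA-style convention, which reduces to the
  plain distance for single pairs and is symmetric in the two selections.
  A restraint is compatible with a conformer when max(0, d - upper) <= 0.3 A
  (the tolerance used when splitting conformer-specific restraint sets;
  exposed as a parameter), giving the four-way classification both /
  IN-specific / OUT-specific / neither.
* **Hydrogen bonds**: backbone N-H donor, oxygen acceptor, H...O < 2.5 A and
  N-H...O angle > 120 degrees per model; a bond is reported when present in
  at least 15/20 of the models (the fraction used when promoting observed
  H-bonds to restraints; a parameter).
* **Buried interfaces**: Shrake-Rupley sphere-sampling SASA with a
  deterministic 960-point golden-spiral sphere, probe 1.4 A, heavy atoms
  only, radii C 1.70 / N 1.55 / O 1.52 / S 1.80 A;
  buried = (SASA_A + SASA_B - SASA_AB)/2. Published interface areas are
  radii-set dependent, which is why the radii are documented here; the
  sampling density reproduces the analytic two-sphere cap to well under 2
  percent.

## Chemical-shift rules

The proline Cb-Cg difference separates trans (4.51 +- 1.37 ppm) from cis
(9.64 +- 1.62 ppm) populations; calls go to the smaller z-score, and a
difference more than 3 standard deviations from both populations is
ambiguous. Cysteine Cb below 32 ppm reads reduced, above 35 ppm oxidized,
ambiguous between. Assignment completeness counts distinct expected
resonances per residue type from a documented inventory (methyl protons one
entry, stereo methylenes two, fast-exchanging OH/SH and Lys NH3+ excluded,
Arg guanidinium NH2 groups collapsed to one observable pair); conventions
differ between laboratories by a few percent, so completeness figures are
comparative, not absolute.

## What the synthetic generators emulate

`synthetic_profile()` describes a ~100-residue IgI-like domain tumbling at
6.6 ns observed at 800.13 MHz: a rigid core (S2 ~ Normal(0.85, 0.03), model
1), disordered tails (residues 1-6 and 96-102; model 3), and an
exchange-broadened five-residue loop (residues 73-77; model 2 with
Rex ~ Uniform(3, 10) s^-1 and S2 ~ Normal(0.80, 0.02)). Noise is 2 percent
on rates and 0.02 absolute on the NOE. The tail parameters are S2 = 0.15
with tau_e = 400 ps: at 800 MHz this puts the back-calculated NOE below zero
with strongly reduced R2, the signature of disordered termini. This is a
deliberate choice — with a longer internal time such as 1 ns the
back-calculated NOE at this field is positive (+0.6), so "low S2 plus long
tau_e" alone does not produce negative NOEs; the internal time must sit in
the few-hundred-ps window.

`gen_two_conformer_ensemble()` builds a 25-residue polyalanine-like hairpin
whose 5-residue loop sits near one strand (IN) or bulges toward the other
(OUT), the central CA moving by > 2 A, with restraint sets derived from the
ideal coordinates (upper = true distance + 0.2 A) chosen so each
conformer-specific set is satisfied only in its own ensemble at the 0.3 A
tolerance. `gen_shift_table()` draws proline Cb-Cg differences from the two
published Normal populations.

What the generators do **not** emulate: physically realistic covalent
geometry or force-field energetics, spectral overlap and peak-picking
errors, anisotropic tumbling, correlated noise between R1/R2/NOE of one
residue, conformational-exchange averaging of chemical shifts, or partial
assignments. Passing recovery tests therefore demonstrates that the
estimators invert their own forward models under realistic noise — not that
every systematic effect present in real spectra is handled.

## Problem sizes and numerical choices

The test-suite simulations use sizes chosen to make sampling error small
relative to the tested tolerances while keeping the default run
desk-friendly: 100-seed replicates for recovery and selection statistics,
n_sim = 500 for in-test critical chi-squares (2000 where the chi-square(2)
limit itself is the target), 200 replicates for decay-rate recovery, and a
3000-start iteratively refined rotation grid as the superposition oracle.
Optimizer settings (multi-start grids per model, bounded nlminb with
rel.tol 1e-12 and a final polish from the winner) are fixed, not adaptive.
Ties and degenerate inputs all have documented deterministic outcomes:
model-2-vs-3 ties go to model 2, model-4-vs-5 ties to model 4, zero
complex-model chi-square yields p = 0 with a warning, a zero NOE reference
volume or an unachievable R2/R1 ratio flags the residue rather than raising,
and generators always restore the caller's RNG state.

## Known limitations

Fully anisotropic (rhombic) diffusion is out of scope, as are
cross-correlated relaxation, reduced spectral-density mapping, simultaneous
optimization of the diffusion tensor with per-residue parameters (tau_c is
fixed first, as in the two-step convention), hydrodynamic prediction of
tau_c from molecular weight, NOE peak assignment/calibration, structure
refinement, and chemical-shift-based dihedral prediction. The
assignment-completeness inventory is one documented convention among
several. Deposited-ensemble comparisons (RMSD to published structures,
inertia ratios of deposited coordinates) require the user to supply the
coordinate files; the package ships no third-party data.
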