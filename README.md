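# igdyn

NMR relaxation and two-conformer ensemble analysis for immunoglobulin-like
protein domains.

Small (~100 aa) beta-sandwich domains of the intracellular immunoglobulin
(IgI) fold are the workhorse building blocks of giant muscle proteins such
as titin. Solution NMR can resolve both their ps-ns backbone dynamics
(through 15N R1, R2 and the 1H-15N heteronuclear NOE) and, when distinct
NOE networks survive conformational averaging, alternative loop conformers
within one calculated structure family. igdyn packages the complete
quantitative pipeline for such a study, for NMR spectroscopists and
structural biologists who want each stage scripted, tested and reproducible:

* mono-exponential fitting of pseudo-3D peak-volume decays to R1/R2 with
  fit-covariance errors, and heteronuclear NOE ratios with
  replicate-difference errors;
* rotational diffusion: apparent per-residue correlation times and a global
  tau_c from R2/R1 ratios (NOE > 0.6 filter), inertia-tensor principal
  axes, and spherical vs. axially symmetric tensor comparison by F-test;
* per-residue Lipari–Szabo model-free analysis, models 1–5, with
  F-statistic selection for models 1–3 and Monte-Carlo critical chi-square
  gating for the zero-degree-of-freedom models 4–5;
* ensemble geometry: Kabsch superposition, per-residue and global RMSD,
  IUPAC phi/psi dihedrals and circular differences, NOE distance-restraint
  evaluation with r^-6 pseudo-atom averaging, conformer-specificity
  classification at a 0.3 A tolerance, geometric H-bond detection, and
  buried interface areas from sphere-sampling solvent accessibility;
* chemical-shift rules: proline cis/trans from the Cb-Cg difference
  (trans 4.51 ± 1.37 ppm, cis 9.64 ± 1.62 ppm), cysteine redox state,
  assignment-completeness statistics;
* synthetic-data generators that emulate the statistical structure of every
  input, so the whole pipeline is testable offline.

The core model is the Lipari–Szabo spectral density with the 2/5
normalization,

    J(w) = (2/5) [ S^2 tau_c / (1 + (w tau_c)^2) + A tau' / (1 + (w tau')^2) ],

entering the standard dipolar + CSA expressions for R1, R2 (+ Rex) and the
NOE; see the methods vignette (`vignettes/igdyn-methods.Rmd`) for the exact
rate equations, the selection scheme's degree-of-freedom bookkeeping and
every convention and default.

## Worked example

```r
library(igdyn)
fc   <- field_context(800.13)          # 800 MHz, rNH 1.02 A, CSA -160 ppm
prof <- synthetic_profile()            # IgI-like domain: rigid core,
                                       # mobile tails, exchanging loop
d    <- gen_relaxation_dataset(prof, seed = 7)

fit <- fit_isotropic(d$records, fc, noe_cutoff = 0.6)
fit
#> <diffusion_model sphere> tau_c = 6.644 +- 0.012 ns, chi2 = 913 (n = 89)

mf <- fit_modelfree_table(d$records[c(2, 50, 75), ], tau_c = fit$tau_c, fc,
                          n_sim = 300, seed = 7)
mf[, c("residue_id", "model", "S2", "te_ps", "Rex", "chi2", "chi2_crit")]
#>   residue_id model    S2 te_ps  Rex   chi2 chi2_crit
#> 1          2     3 0.144   397   NA 0.0249      4.07
#> 2         50     1 0.799    NA   NA 3.3493      6.76
#> 3         75     2 0.857    NA 3.74 0.1275      3.77
```

The generating profile tumbles at 6.6 ns; the ratio fit recovers 6.64 ns
from 89 residues (the exchange-broadened loop passes the NOE filter and
inflates the fit chi-square, exactly as in experimental data). The three
residues show the three regimes: a disordered tail residue (model 3, low S2
with a ~400 ps internal time), a rigid core residue (model 1), and a loop
residue carrying Rex ~ 4 s^-1 (model 2) — each selected model's chi-square
sits below its Monte-Carlo critical value.

The shift-classification rules run directly on tabulated assignments, here
the proline Cb/Cg pairs of the titin I82 construct shipped with the package:

```r
shifts <- read_shift_table(system.file("extdata", "i82_proline_shifts.tsv",
                                       package = "igdyn"))
cb <- shifts[shifts$atom_name == "CB", ]
cg <- shifts[shifts$atom_name == "CG", ]
m  <- merge(cb, cg, by = "residue_number")
cbind(residue = m$residue_number, proline_isomer(m$ppm.x, m$ppm.y))
#>   residue delta z_trans z_cis  call
#> 1       4   5.3  0.5766  2.68 trans
#> 2       9   4.5  0.0073  3.17 trans
#> 3      35   5.3  0.5766  2.68 trans
#> 4      50   3.4  0.8102  3.85 trans

circular_difference(84, -70)   # psi(G76) between the IN / OUT conformers
#> [1] 154
```

All four prolines classify trans, and the flipped peptide group at the
glycine of the EF-loop shows up as a ~150 degree psi change between the two
conformers.

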