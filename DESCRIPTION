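Package: igdyn
Title: NMR Relaxation and Two-Conformer Ensemble Analysis for
    Immunoglobulin-Like Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of backbone amide 15N spin relaxation
    and multi-conformer NMR ensembles of small beta-sandwich protein
    domains.  Implements mono-exponential fitting of pseudo-3D peak-volume
    decays, heteronuclear NOE ratios with replicate-difference errors,
    rotational-diffusion characterization (correlation time from R2/R1
    ratios, inertia-tensor principal axes, sphere versus axially symmetric
    tensor comparison by F-test), per-residue Lipari-Szabo model-free
    fitting of motional models 1-5 with F-statistic and Monte-Carlo
    critical chi-square model selection, ensemble superposition and
    per-residue RMSD, backbone dihedral and circular-difference analysis,
    NOE distance-restraint evaluation with r^-6 pseudo-atom averaging and
    conformer-specificity classification, geometric hydrogen-bond
    detection, buried-interface areas from sphere-sampling solvent
    accessibility, chemical-shift classification rules (proline cis/trans,
    cysteine redox state, assignment completeness), and synthetic-data
    generators that emulate the statistical structure of real relaxation
    and ensemble data so every stage can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
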