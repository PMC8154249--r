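Package: vbwsas
Title: Variational Bayesian Ensemble Weighting for Small-Angle Scattering of
    Disordered Protein Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global analysis of absolute-scale small-angle X-ray scattering
    (SAXS) series measured on intrinsically disordered proteins that populate
    monomeric and multimeric conformers. Couples a mass-action thermodynamic
    model of the conformer populations (Gibbs-Helmholtz parameterized standard
    enthalpy, entropy and heat capacity changes) with a variational Bayesian
    Dirichlet treatment of the within-class conformer weights, a Debye-sum
    form-factor engine with a tunable hydration shell, and an interacting
    solution model built from the Percus-Yevick hard-sphere structure factor
    perturbed by two Yukawa potentials in the random phase approximation with
    ellipsoidal decoupling. Includes ensemble-weighted Ramachandran propensity
    analysis, a synthetic-data generator for multimeric toy ensembles and
    simulated scattering series, global fitting by simulated annealing with
    simplex refinement, regularization across neighboring conditions, and
    parametric-bootstrap uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
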