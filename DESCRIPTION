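Package: pfasER
Title: QSPR/QSAR Modelling of PFAS Binding to Estrogen Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative structure-property/activity relationship (QSPR/QSAR)
    modelling of per- and polyfluoroalkyl substance (PFAS) binding to the
    estrogen receptors ERalpha and ERbeta. Converts docking scores to IC50 and
    pIC50 units and validates the conversion against experimental affinities;
    performs variance-inflation-factor guided descriptor selection; fits and
    evaluates multiple-linear-regression models with leave-one-out Q2,
    Williams-plot applicability-domain diagnostics and accumulated local
    effects profiles; validates models through pairwise ensemble splits,
    docking-score cutoffs with iterative outlier refinement, and active/decoy
    benchmark separation; and profiles ligand-residue contacts in receptor
    complexes. Ships the four published reference equations and a synthetic
    data generator with known ground truth so every stage is testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, bio3d, rlang
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'affinity.R'
    'descriptors.R'
    'qspr-mlr.R'
    'ale.R'
    'applicability-domain.R'
    'io.R'
    'model-validation.R'
    'synthetic-data.R'
    'pipeline.R'
    'structure-contacts.R'
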