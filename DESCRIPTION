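Package: spinlabelr
Title: Rotamer-Library Spin-Label Predictions of DEER and PRE Data from
    Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places nitroxide spin-label rotamers on protein structures and
    conformational ensembles using a rotamer-library approach, weighting each
    conformer by its intrinsic Boltzmann probability and a Lennard-Jones
    steric energy against the protein. From the resulting label ensembles it
    predicts double electron-electron resonance (DEER) distance distributions
    and dipolar time traces via the Fresnel-integral kernel, and paramagnetic
    relaxation enhancement (PRE) transverse rates and HSQC intensity ratios
    via Solomon-Bloembergen theory with a model-free treatment of label
    motion. Supports multi-frame ensembles (multi-model PDB, DCD) with frame
    reweighting and steric-partition-function filtering, and ships
    deterministic synthetic-fixture generators for testing.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
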