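Package: FlexField
Title: Deformation-Field Analysis of Continuous Conformational Heterogeneity
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for representing, fitting and analysing molecular
    deformation fields from continuous-heterogeneity cryo-EM studies.
    Implements the 3D Zernike polynomial deformation-field model (basis
    evaluation on atoms or voxels, least-squares coefficient fitting,
    application of fields to structures and density maps), elastic-network
    normal-mode analysis (anisotropic and Gaussian network models with mode
    editing, fluctuations and cross-correlations), bidirectional
    least-squares interconversion between normal-mode amplitudes and Zernike
    coefficients, reassignment of deformation fields to a new reference
    conformation, focused (mask-restricted) landscape re-fitting, and a
    landscape-analysis toolbox: per-point motion statistics, RMSD-threshold
    clustering of conformers, best-view selection by projection correlation,
    PCA reduction of coefficient landscapes and k-means representatives.
    Includes seeded synthetic-data generators for every input class so all
    analyses run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, bio3d, jsonlite, pracma
Suggests: testthat (>= 3.0.0), MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'io-pdb.R'
    'io-mrc.R'
    'io-table.R'
    'zernike-basis.R'
    'zernike-field.R'
    'enm.R'
    'conversion.R'
    'reassignment.R'
    'ensemble.R'
    'landscape.R'
    'fixtures.R'
    'cli.R'
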