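Package: receptorModes
Title: Collective Mode Analysis of Chemoreceptor Dimer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the collective conformational dynamics of
    homodimeric four-helix-bundle receptors such as the bacterial
    chemoreceptor Tar periplasmic domain. Reads structures and structural
    ensembles (multi-model PDB or coordinate tables), selects C-alpha sites
    over configured helix ranges, and extracts dominant collective modes by
    principal component analysis of superposed ensembles and by anisotropic
    network model normal mode analysis of single structures. Builds a piston
    vector from an apo/holo structure pair, quantifies mode overlaps,
    projects ensembles onto a two-dimensional rotation/piston landscape,
    clusters that landscape by local density peaks, clusters conformations
    by distance-RMS cutoff, and measures anti-symmetric binding-pocket
    geometry changes along modes. Includes a synthetic-ensemble generator
    with planted, correlated rotation and piston modes so that every
    pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'structure_io.R'
    'geometry.R'
    'ensemble_modes.R'
    'enm.R'
    'piston.R'
    'basis_io.R'
    'landscape.R'
    'pockets.R'
    'synthetic.R'
    'pipeline.R'
    'receptorModes-package.R'
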