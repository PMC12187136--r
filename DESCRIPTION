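Package: vwmdyn
Title: Dynamics of Visual Working Memory Codes from Multivoxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the temporal dynamics of orientation
    working-memory codes in multivoxel fMRI patterns. Implements periodic
    support vector regression of circular orientation labels with the
    feature continuous accuracy (FCA) metric, temporal cross-decoding
    matrices with cluster-based sign-permutation statistics and a
    conjunction definition of dynamic-coding elements, PCA neural
    subspaces compared through split-half above-baseline principal
    angles, permutation-based split-half voxel reliability selection,
    and noise-level cross-decoding simulations. A synthetic-data
    generator with known ground truth (orientation tuning, code
    rotation, distractor geometry, signal-to-noise ratio) makes every
    stage testable without access to empirical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
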