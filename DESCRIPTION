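Package: netlag
Title: Lagged Inter-Network Functional Connectivity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state fMRI network connectivity analysis:
    temporal-concatenation group spatial ICA with back-reconstruction and
    template-based network identification; voxelwise intra-network group
    statistics with permutation cluster-level familywise-error control;
    and inter-network coupling via the constrained maximal lagged
    (circularly shifted) Pearson correlation with Fisher z group ANCOVA,
    pairwise contrasts and brain-behaviour partial correlations. Includes
    a synthetic multi-subject BOLD cohort generator with known ground
    truth (spatial networks, group-specific amplitude deficits, lagged
    inter-network couplings and matched phenotype covariates) so the full
    pipeline is testable end-to-end, plus NIfTI-1/TSV/JSON readers and
    writers and a seeded pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
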