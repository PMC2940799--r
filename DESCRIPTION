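Package: kernelCNA
Title: Kernel-Convolution Detection of Recurrent Copy-Number Aberrations
    with Cross-Species Synteny Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects recurrent DNA copy-number gains and losses in groups
    of array-CGH tumor profiles by convolving per-probe aggregate log2
    ratios with a Gaussian kernel and calibrating a genome-wide
    significance threshold from the permutation distribution of maximum
    smoothed peak heights. A comparative mode contrasts two tumor groups
    position-by-position through a signal-to-noise ratio of per-sample
    smoothed profiles with class-label-permutation control of the false
    discovery rate. Additional tools quantify per-tumor genomic
    instability (aberrant probe fractions, threshold sweeps of smoothed
    aberration counts, Welch contrasts), map significant regions between
    two genomes through ortholog tables with synteny-block inversion
    flags, and simulate two-species BAC-array cohorts with planted
    aberrations and known synteny structure for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
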