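Package: astroquant
Title: Quantification of Astrocyte Immunofluorescence and ATP-Evoked Calcium Transients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying marker-positive cells, area coverage and
    marker co-localization in multichannel immunofluorescence micrographs of
    stem-cell-derived astrocyte cultures, and for decomposing ATP-evoked
    calcium fluorescence transients into kinetic components (latency, 10-90%
    rise time, exponential decay tau, area under the curve, monophasic or
    biphasic class). Includes ground-truthed simulators for both data types,
    Otsu thresholding with a Pearson-correlation quality-control loop,
    group-level statistics (ANOVA with Bonferroni post hoc, Mann-Whitney)
    and a reproducible end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
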