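Package: nphys
Title: Quantification of Neuronal Excitability, Calcium Activity, Microexon
    Splicing and Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and group statistics for slice
    electrophysiology and in vivo imaging studies of cortical interneurons.
    Extracts passive membrane properties, action-potential features,
    input-output curves, rheobase and fast-spiking classification from
    current-clamp step protocols; quantifies somatic calcium activity from
    ROI fluorescence traces as dF/F0 transients (AUC, amplitude, duration,
    frequency); computes exon percent-spliced-in from junction read counts
    and RT-PCR band intensities with Fisher-exact differential tests;
    derives Y-maze alternation, elevated-plus-maze and gait metrics; and
    ties them together with Mann-Whitney, mixed two-way ANOVA and
    Benjamini-Hochberg machinery. Leaky integrate-and-fire and Poisson
    calcium-event simulators provide exact ground truth so every stage is
    verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
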