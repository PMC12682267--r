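Package: msnephys
Title: Current-Clamp Spike-Train and Evoked-PSP Analysis for Striatal Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of whole-cell current-clamp recordings from striatal
    medium spiny neurons under paired optogenetic stimulation. Provides
    action-potential detection and per-train feature extraction (latency,
    inter-spike interval, spike geometry), depolarization-block detection via
    a bimodal spike-height histogram, paired light/no-light input-output
    curve construction, classification of optogenetically evoked postsynaptic
    potentials as excitatory, mixed, or inhibitory, and the accompanying
    nonparametric statistics (Wilcoxon signed-rank, Mann-Whitney U,
    Bonferroni correction, two-way OLS ANOVA, chi-squared tests). A
    synthetic-data module generates sweep cohorts with known ground truth so
    every analysis stage has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
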