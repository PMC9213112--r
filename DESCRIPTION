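Package: brillquant
Title: Quantification of Confocal Brillouin Microscopy Maps of Cartilage
Version: 0.1.0
Authors@R:
    person("Axolotl", "Mechanics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of confocal Brillouin
    microscopy frequency-shift maps of cartilaginous tissue. Converts
    measured Brillouin frequency shifts to the dimensionless elastic
    contrast, the longitudinal modulus and the longitudinal
    compressibility; reads and writes shift maps, label masks and cohort
    tables as plain CSV; quantifies maps by rectangular regions of
    interest, cell-versus-matrix masks and size-normalized transversal
    line profiles; and provides a small-sample nonparametric statistics
    suite (Friedman with Kendall's W, Kruskal-Wallis with eta squared,
    exact Mann-Whitney with effect size r, Dunn's post hoc tests,
    Chen-Shapiro normality screening). A synthetic tissue-phantom
    generator emulates collagenase digestion, digit development and
    digit regeneration experiments so the full pipeline can be exercised
    end-to-end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
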