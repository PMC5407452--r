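Package: baltatlas
Title: Sigmoid Transition Modelling and Candidate Screens for a Fetal
    Adrenal and Gonad Expression Atlas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing developmental time-series expression atlases
    of the human fetal adrenal gland, testis and ovary. Implements the
    four-parameter BALT sigmoid model of per-gene expression transitions
    (basis, amplitude, localisation, transition) with Levenberg-Marquardt
    fitting, BIC model selection, Metropolis MCMC uncertainty intervals and
    dynamic-profile classification; empirical-Bayes moderated two-group
    differential expression with Benjamini-Hochberg FDR and the fold-change
    threshold screens used to derive steroidogenesis candidate gene lists;
    batch adjustment, outlier detection, PCA and Ward clustering for sample
    QC; and a seed-reproducible synthetic atlas generator with planted ground
    truth mirroring the study design (53 samples, 42-74 days post conception).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    limma,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
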