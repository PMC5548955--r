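Package: trapshift
Title: Cell-Type-Specific TRAP-Seq Differential Translation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for translating ribosome affinity
    purification (TRAP) sequencing experiments with a paired
    knockout/wild-type littermate design.  Provides paired
    negative-binomial differential expression of immunoprecipitated (IP)
    and Input fractions, an abundance-window-matched cumulative
    fold-change distribution shift test for target gene sets with a
    random-gene-set resampling null, Pfam-clan Fisher enrichment against
    an expressed-gene background, exact 2x2 contingency statistics for
    seizure-incidence tables, TPM quantification, and a synthetic count
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
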