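Package: tonosieve
Title: Candidate Nomination for Tonoplast Microautophagy in Maize Aleurone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a multi-omic candidate-prioritization
    pipeline for proteins potentially involved in microautophagy at the maize
    aleurone tonoplast. Provides replicate-aware TPM summarization with a
    strict all-replicates-expressed rule, tissue-preference Compartment
    (CS) scores, dual-method consensus differential expression between
    aleurone and starchy endosperm (negative-binomial GLM likelihood-ratio
    tests and precision-weighted moderated t-statistics on paired designs),
    confidence tiering of co-immunoprecipitation proteomics against a
    pre-immune control with add-one pseudocount fold differences, one-sided
    Fisher's exact tonoplast-proteome enrichment, DAG-aware GO term
    enrichment (classic and weight01 decorrelated Fisher tests),
    fluorescence fold-enrichment statistics for double-membrane engulfment
    domains, comparative-Ct qPCR quantification, and a candidate funnel that
    combines all evidence streams. A synthetic-data module generates every
    input with known ground truth so each stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
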