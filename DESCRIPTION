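Package: MetabolizR
Title: Rule-Based Prediction of Xenobiotic Metabolism and MS-Driven
    Metabolite Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A knowledge-based engine for predicting the biotransformation
    of small molecules in human tissues, the human gut microbiome, and the
    environmental microbiome. Biotransformation rules are encoded as
    atom-mapped SMIRKS transforms with separately encoded SMARTS and
    property constraints, organised in JSON rule packs together with
    enzymes, pathways and precedence (relative-reasoning) relations. The
    reasoning engine applies rules at every matching site, deduplicates
    products by InChIKey, enforces rule precedence, and enumerates
    multi-step metabolic trees with full reaction/enzyme provenance.
    Substrate eligibility filters for CYP450 and phase II metabolism are
    included, the latter with a 32-descriptor featurizer and a random
    forest harness. A metabolite identification tool searches predicted
    trees for neutral monoisotopic masses or molecular formulas derived
    from mass spectrometry data and reports the metabolic pathway leading
    to each match.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
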