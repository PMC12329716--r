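Package: redoxomics
Title: Multi-Omics Pipeline Linking Peat Organic-Matter Quality to Microbial
    Redox Metabolism and Methane Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tested implementations of the bespoke computational stages of a
    peat-incubation multi-omics analysis: LC-MS feature-artifact cleaning
    (retention-time binning, co-elution correlation grouping, MS2
    parent-fragment matching, halogen-formula removal), metabolite
    normalization (generalized log, Pareto scaling), nominal oxidation state
    of carbon (NOSC) scoring, per-feature linear contrasts with
    Benjamini-Hochberg correction, KEGG-style pathway logical-expression
    parsing and expression aggregation under geTMM normalization,
    metagenome-assembled-genome (MAG) activity and pathway-encoding curation,
    signed weighted co-expression module detection correlated with methane,
    and Henry's-law dissolved-gas accounting with carbonate speciation. A
    synthetic-data generator emulates every input with ground-truth labels so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
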