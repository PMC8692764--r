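Package: oceanpack
Title: Ontology-Enriched Data Packages for Marine 'Omics Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for creating, validating and querying ontology-enriched
    tabular data packages for marine microbiome studies. A data package pairs a
    JSON descriptor with TSV resources whose columns are annotated with a triad
    of OBO Foundry ontology terms: what the column measures (ENVO/PMO), its
    unit (UO) and the measurement device (OBI). The package checks complete
    transferability (file presence, MD5 checksums), per-cell type, datetime
    format and numeric range constraints, and annotation completeness; builds a
    lightweight ontology term graph with ancestor/descendant closures for
    subsumption-aware attribute discovery; mints chemical concentration terms
    from a solute/material design pattern; harmonizes attributes across
    packages into a sample-by-attribute table with unit conversion and full
    provenance; and provides the downstream statistical layer: nutrient
    stoichiometry regression (Redfield ratio), Spearman correlation,
    climate-zone faceting, relative-abundance normalization, Bray-Curtis
    dissimilarity and a permutational distance-based redundancy analysis with
    per-taxon depth coefficients. Deterministic synthetic-fixture generators
    with ground-truth manifests support oracle-based testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
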