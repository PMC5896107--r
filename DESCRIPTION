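Package: rpsimi
Title: Interoperability for PSI-MI Molecular Interaction Data Formats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A change-resilient interoperability layer for molecular
    interaction data. Provides one abstract, format-agnostic data model and
    version-aware readers and writers for the PSI-MI family of formats:
    MITAB 2.5/2.6/2.7 (read/write), PSI-MI XML 2.5 with the 3.0 additions
    for dual publication representation and abstract interactions
    (read/write), and the write-only MI-JSON and HTML renderings. Includes
    spoke and matrix expansion of n-ary interactions into binary
    interactions, a fetcher-backed enrichment framework with file-backed
    fetchers, a structural and controlled-vocabulary usage validator driven
    by an OBO ontology, a seeded synthetic network generator with
    ground-truth sidecars, and a conversion front end enforcing the
    read/write support matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
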