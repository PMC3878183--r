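Package: elnmanifest
Title: Knowledge-Layer Metadata Manifests for Electronic Laboratory Notebooks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Tools for describing Electronic Laboratory Notebook (ELN)
    records with a compact, machine-readable metadata manifest so that the
    chemistry they contain can be discovered, cited and processed. Provides
    the typed manifest data model, canonical XML serialization with a
    shipped XML Schema Definition, rule-based semantic validation, a Dublin
    Core crosswalk, derivation of manifests from source ELN records (blog-
    style and experiment-database-style), a harvestable feed with filtering,
    pagination and three-tier (knowledge/information/processing) resolution,
    an SDF-based deposition packager that carries author, principal
    investigator and experiment-id provenance in structure-data fields, and
    a deterministic synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
Config/testthat/edition: 3
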