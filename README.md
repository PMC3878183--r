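# elnmanifest

Knowledge-layer metadata manifests for Electronic Laboratory Notebook (ELN)
records.

## The problem

Chemistry ELNs hold a vast body of experimental knowledge that discovery,
citation and data-mining services cannot see, because every ELN product
exposes its records differently. A practical route out is a *tiered*
metadata architecture:

1. a **knowledge layer** — core descriptive metadata, akin to the 15 Dublin
   Core elements, answering *"what is this and is it of interest to me?"*;
2. an **information layer** — contextual links to publications, grants,
   people and related records;
3. a **processing layer** — the detail an agent needs to fetch and
   automatically process the content itself.

`elnmanifest` implements the knowledge layer as a compact, vendor-neutral
manifest — one per ELN unit (`Package` of records, single `Record`, or
`Component` such as a spectrum) — with mandatory
`Title`, `Identifiers`, `Contact`, `Contributors`, `Source`, `Date` and
`Content` parts and optional `Keywords`, `LicensingBasis` and
`RelatedItems`. The manifest's `relatedItems` element is the route into the
information layer; its `content` list (description + MIME type + optional
locator per item), together with the optional open-access
`accessIdentifier`, is the access point to the processing layer.

The package provides:

* the typed manifest model with constructor-enforced invariants
  (`eln_manifest()` and friends);
* a canonical, byte-deterministic XML dialect with a shipped XSD
  (`manifest_to_xml()`, `manifest_from_xml()`, `validate_xml()`);
* rule-based semantic validation with severities and element paths
  (`validate_manifest()`);
* a crosswalk onto the 15 Dublin Core elements (`dc_crosswalk()`);
* derivation of manifests from source ELN records — blog-style exports and
  experiment-database plugins with a site configuration file and
  per-deposition user input (`derive_manifest()`, `load_site_config()`);
* embargo arithmetic: `releaseDate = compute_release_date(creationDate,
  embargo)` with ISO 8601 durations and month-end clamping;
* an OAI-PMH-style harvest feed over a manifest store with filtering,
  pagination via resumption tokens, and three-tier resolution
  (`list_manifests()`, `resolve_tier()`);
* SDF deposition packaging carrying `AUTHOR`, `PRINCIPAL_INVESTIGATOR` and
  `ELN_EXPERIMENT_ID` data fields in every structure record, plus the
  inverse splitter (`package_deposition()`, `split_deposition()`);
* a deterministic synthetic fixture generator (`fixture_profile()`,
  `generate_store()`, `generate_molfile()`).

A command-line interface wrapping these functions ships at
`inst/cli/elnmanifest.R` (subcommands `validate`, `crosswalk`, `derive`,
`harvest`, `resolve`, `deposit`, `gen-fixtures`).

## A worked example

```r
library(elnmanifest)

m <- eln_manifest(
  unitType = "Record",
  title = "Spectrum of bromophenyl dihydroindolone",
  identifiers = eln_identifier_set(
    "http://eln.example.org/notebook/5606/spectrum.html",
    accessIdentifier = "http://data.example.org/eln/5606"),
  contact = eln_contact("EMail", "curator@example.org"),
  contributors = list(eln_contributor("Author", "A. Chemist"),
                      eln_contributor("PI", "F. Willoughby")),
  source = "OpenBlogELN/2.3",
  dates = eln_date_set(as.Date("2013-08-01"),
                       releaseDate = compute_release_date(as.Date("2013-08-01"), "P6M")),
  licensingBasis = "CC-BY-4.0",
  content = list(eln_content_item("Record body", "text/html"),
                 eln_content_item("Structure file", "chemical/x-mdl-sdfile")))
m
#> <elnItemManifest unitType="Record">
#>   Title:      Spectrum of bromophenyl dihydroindolone
#>   Identifier: http://eln.example.org/notebook/5606/spectrum.html
#>   Access:     http://data.example.org/eln/5606
#>   Contact:    EMail: curator@example.org
#>   Source:     OpenBlogELN/2.3
#>   Created:    2013-08-01
#>   Released:   2014-02-01
#>   License:    CC-BY-4.0
#>   Contributors (2): A. Chemist (Author); F. Willoughby (PI)
#>   Content items (2): text/html, chemical/x-mdl-sdfile
```

The release date was computed from a six-month embargo on the creation
date; month arithmetic clamps to valid days, so
`compute_release_date(as.Date("2013-08-31"), "P6M")` is `2014-02-28`.
Validation confirms the manifest is publishable:

```r
validate_manifest(m)
#> <eln_validation_report> valid: TRUE (0 error(s), 0 warning(s))
```

and the Dublin Core crosswalk flattens it for a generic repository
(role Author maps to `creator`, every other role to `contributor`; content
media types land on `format`):

```r
dc_crosswalk(m)
#>        element                                              value
#> 1        title            Spectrum of bromophenyl dihydroindolone
#> 2   identifier http://eln.example.org/notebook/5606/spectrum.html
#> 3   identifier                   http://data.example.org/eln/5606
#> 4      creator                                         A. Chemist
#> 5  contributor                                      F. Willoughby
#> 6       rights                                          CC-BY-4.0
#> 7       source                                    OpenBlogELN/2.3
#> 8         date                                         2013-08-01
#> 9       format                                          text/html
#> 10      format                              chemical/x-mdl-sdfile
#> 11        type                                             Record
```

`resolve_tier(m, "information")` returns the related-item list and
`resolve_tier(m, "processing")` the content items plus the access
identifier — the entry points to the two lower layers.

## Vignette

`vignettes/eln-metadata-manifests.Rmd` documents the metadata model, the
design decisions behind the XML dialect and validation rules, what the
synthetic fixtures do and do not emulate, and known limitations.
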