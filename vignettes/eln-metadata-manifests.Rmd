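---
title: "Knowledge-layer metadata manifests for ELN records: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-layer metadata manifests for ELN records: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elnmanifest)
```

## The problem and the model

Electronic Laboratory Notebooks accumulate enormous amounts of chemical
information that stays invisible to discovery, citation and automated
processing services, because each ELN product exposes its records in its own
way. `elnmanifest` implements a tiered answer to that problem. Metadata about
an ELN unit is organised in three layers:

* the **knowledge layer** — a compact, generic summary that lets a person or
  a harvesting agent decide quickly whether a record is of interest and how
  to cite it;
* the **information layer** — contextual links connecting the record to
  publications, grants, facilities and related work;
* the **processing layer** — the detail needed to fetch and machine-process
  the content itself.

The manifest implemented here *is* the knowledge layer. Its `relatedItems`
element is the route into the information layer, and its `content` list —
one entry per constituent item, each with a human-readable description, a
media type and an optional locator — together with the optional
`accessIdentifier` is the access point to the processing layer.
`resolve_tier()` makes these three projections explicit.

A manifest describes one *unit*, qualified by `unitType`: a `Package` of
several records, a single `Record`, or a `Component` of a record such as a
spectrum or a reaction. The mandatory parts are the unit type, a title, the
identifier set (with a mandatory primary local identifier), a contact, at
least one contributor, the generating-system string, the date set (with a
mandatory creation date) and at least one content item. Keywords, a
licensing basis, related items, alternative and access identifiers, and the
release/publication/submission dates are optional.

## Design decisions

The underlying element table leaves several points open; the package fixes
them as follows.

**Element naming and casing.** Prose and table casing are inconsistent in
descriptions of this schema (e.g. `elnItemManifest` vs `Title`). The XML
dialect uses camelCase for the root and for compound leaf names that are
conventionally written that way (`elnItemManifest`,
`PrimaryLocalIdentifier` stays initial-capital as a Qualifier name), and
initial capitals for the table-level elements (`Title`, `Keywords`,
`Identifiers`, `Contact`, `LicensingBasis`, `Contributors`, `Source`,
`Date`, `RelatedItems`, `Content`). One convention, fixed in the shipped
XSD, is what matters for interoperability.

**`unitType` as an attribute.** The unit type qualifies the manifest as a
whole, not any one child, so it is carried as an attribute of the root
element rather than as an element.

**Namespace.** The dialect namespace is the project-chosen constant
`urn:eln-item-manifest:1.0` with a `schemaVersion` attribute on the root.
A URN was preferred over an `http:` URL because no stable hosting location
exists to dereference; versioning happens through `schemaVersion` and the
XSD file shipped in `inst/extdata/`.

**Dates and durations.** Dates are ISO 8601 calendar dates (`YYYY-MM-DD`),
matching data-citation practice. One date per kind is allowed
(creation, release, publication, submission); multiple dates of the same
kind are deliberately not modelled pending a use case. Embargo periods are
ISO 8601 date durations (`P6M`, `P1Y2M`, `P14D`); time-of-day components
are rejected because embargoes are whole calendar days.
`compute_release_date()` advances the creation date by calendar arithmetic
with month-end clamping: six months after 2013-08-31 is 2014-02-28. The
creation date is used as the embargo base because it is the only mandatory
date available at deposition time.

**Validation severities.** "DOI preferred" for publication-related items is
a warning, not an error, since any string is a legal id. A related item is
treated as a publication when its relationship string equals
`"publication"` case-insensitively; DOIs are recognised in bare, `doi:` and
`https://doi.org/` forms. Contributor roles are free text — imposing a
controlled vocabulary would be premature — so unrecognised roles warn only.
Date-order checking applies only to creation vs release; publication and
submission dates are unordered relative to release, because an article may
be submitted before or after the ELN record opens. E-mail validation is
syntactic (one `@`, non-empty parts): full RFC 5322 validation is out of
proportion for metadata.

**Tolerant reading.** Foreign-namespace elements are ignored with a warning
on read and never written, so locally extended documents still harvest;
unknown elements *in* the manifest namespace are an error, since they
indicate version skew rather than extension.

**Derivation.** The record body is always emitted as a content item, so the
mandatory content list is non-empty even for attachment-free records — the
narrative itself is part of what the manifest describes. Attachment media
types are taken verbatim from the source; a missing type becomes
`application/octet-stream` with a warning. The user-entered licensing basis
wins over anything recorded in the source system, because licensing may
change from one deposition to the next. The site configuration file is a
flat `key = value` text format (see `save_site_config()`), easily edited
from an ELN plugin interface.

**Harvest feed.** The feed is deliberately file/directory-backed (a folder
of manifest XML documents) rather than a network service: harvesting is
specified abstractly as push or pull over manifests, and a thin HTTP layer
can wrap `read_store()`/`list_manifests()` later. Pagination follows the
list/resume pattern of OAI-PMH without claiming protocol conformance:
resumption tokens are opaque strings binding a filter fingerprint and an
offset, and a token presented under a different filter or page size is
rejected. Embargo enforcement is a feed-level constraint
(`requireReleased`) rather than suppression at serialization, so private
harvesting of embargoed records remains possible. All filter matching is
case-sensitive except the license prefix, where `cc-by` should find
`CC-BY-4.0`.

**Knowledge-tier view.** `resolve_tier(m, "knowledge")` removes the related
items and the content locators but keeps content descriptions and media
types, since "what kinds of thing does this record contain" is discovery
information. A consequence worth noting: the Dublin Core crosswalk of the
knowledge view equals the crosswalk of the full manifest on every element
except `relation` (which comes from the removed related items); the tests
assert exactly that.

**Deposition packaging.** A deposition is a single SDF carrying every
structure plus a separate manifest XML file. The three provenance data
fields are fixed tags `AUTHOR`, `PRINCIPAL_INVESTIGATOR` and
`ELN_EXPERIMENT_ID` — their meanings are prescribed, their spellings are a
package choice — and they are replicated into every SDF record because SDF
consumers commonly split files record-wise. The author field takes the
first contributor with role Author, falling back to the first contributor;
the PI field takes the first PI/Principal Investigator and is present but
empty when there is none. Molfiles are treated as opaque validated text
(V2000 counts-line check only) and preserved byte-for-byte through
package/split; chemical perception is deliberately out of scope.

## The synthetic fixture generator

`fixture_profile()` describes a synthetic open-notebook project. Generation
is counter-based: every drawn value is a pure function of
`(seed, index, fieldName)` through a 32-bit FNV-1a hash, so any record can
be regenerated in isolation, independent of generation order, global RNG
state, locale or wall clock.

Defaults model a mid-size two-year project of 50 records
(2012-01-01 to 2013-12-31), alternating between the two source styles the
derivation supports: blog-style records with permalink-URL identifiers and
HTML bodies, and experiment-database records with `EXP-NNNN` identifiers.
Attachment probabilities per record are 0.4 (SDF), 0.3 (CML), 0.5 (PNG),
0.35 (CSV) and 0.25 (PDF) — roughly one structure file every two to three
records and images on half, which is what open-notebook chemistry feeds
look like; 30% of depositions carry an embargo (drawn from 14 days to one
year) and 40% link a publication DOI. These rates are the study conditions
of the test suite, chosen once.

`generate_store()` derives manifests strictly through `derive_manifest()`,
so it exercises exactly what an ELN export can produce.
`generate_manifest()` additionally draws the fields derivation cannot reach
(keywords, alternative and access identifiers, publication and submission
dates) for property tests of serialization, crosswalk and tier resolution.
`generate_molfile()` emits structurally valid V2000 chains of C/N/O atoms
on a grid — parseable by any molfile reader, chemically meaningless by
design.

What the fixtures do **not** emulate: real heterogeneous payloads (spectra,
CIF, AniML), messy human titles and author spellings, records edited after
creation, or malformed exports from real ELN software. Passing tests
therefore demonstrate the correctness of the manifest machinery, not
robustness to arbitrary real-world ELN exports.

## Numerical and procedural choices

* Serialization is canonical and byte-deterministic (pretty-printed UTF-8,
  no BOM); equality of manifests is structural (`identical()` on the
  normalised objects), and the round trip `from_xml(to_xml(m))` is the
  identity on valid manifests.
* Feed ordering is by `(lastModified, storeId)` with timestamps compared in
  UTC, so pagination is stable across time zones.
* Month arithmetic clamps to the last valid day of the target month before
  day/week offsets are applied; the tests cross-check against an
  independent oracle that derives month lengths a different way (first of
  next month minus one day) and, in the suite's frozen cases, values
  verified against a third-party calendar library.
* Problem sizes in the tests — 50-record default stores, 500 round-trip
  manifests, 100-manifest feed sweeps with 50 random filters, 100
  deposition packages, 1000 embargo cases — were chosen to exercise every
  code path and probability branch of the generator while keeping the suite
  comfortably interactive.

## Known limitations

* One date per kind; multiple submission venues cannot be recorded.
* No RDF/linked-data serialization and no Qualified Dublin Core; the
  crosswalk targets the 15-element set only.
* The feed implements list/resume semantics only — no full OAI-PMH verb
  set, no SWORD deposit.
* Identifiers are never dereferenced; validation is purely syntactic.
* Only chemical structures are packaged for deposition; spectra, reactions
  and property datasets would need their own packaging conventions.
* Contact details are included in the knowledge-layer view; a
  privacy-filtering option would be a straightforward extension.

## A worked example

```{r example}
src <- eln_record_source(
  localId = "http://eln.example.org/notebook/5606/spectrum.html",
  title = "Spectrum of bromophenyl dihydroindolone",
  authors = list(c("Author", "A. Chemist")),
  createdOn = as.Date("2013-08-01"),
  systemName = "OpenBlogELN", systemVersion = "2.3",
  attachments = list(list(filename = "s.sdf",
                          mediaType = "chemical/x-mdl-sdfile",
                          description = "Structure file",
                          locator = "http://eln.example.org/files/s.sdf")))
m <- derive_manifest(src, fixture_site_config(),
                     eln_user_input("CC-BY-4.0", "P6M"))
m
validate_manifest(m)
dc_crosswalk(m)
resolve_tier(m, "processing")
```
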