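# Shared helpers: small manifest builders, an independent calendar oracle,
# and a naive full-scan feed oracle used to cross-check the paginated feed.

`%||%` <- function(a, b) if (is.null(a)) b else a

minimal_manifest <- function() {
  eln_manifest(
    unitType = "Record",
    title = "Spectrum of bromophenyl dihydroindolone",
    identifiers = "http://eln.example.org/notebook/5606/spectrum.html",
    contact = eln_contact("EMail", "curator@example.org"),
    contributors = eln_contributor("Author", "A. Chemist"),
    source = "OpenBlogELN/2.3",
    dates = eln_date_set(as.Date("2013-08-01")),
    content = eln_content_item("Record body", "text/html"))
}

complete_manifest <- function() {
  eln_manifest(
    unitType = "Record",
    title = "Synthesis of methyl oxime",
    keywords = c("oxime", "NMR"),
    identifiers = eln_identifier_set(
      "EXP-1042", otherLocalIdentifiers = "hdl:20.1000/alt-1042",
      accessIdentifier = "http://data.example.org/eln/1042"),
    contact = eln_contact("SystemURI", "http://eln.example.org/contact"),
    licensingBasis = "CC-BY-4.0",
    contributors = list(eln_contributor("Author", "A. Chemist",
                                        "https://orcid.org/0000-0001-0000-0002"),
                        eln_contributor("PI", "F. Willoughby")),
    source = "ExperimentDB/9.2.0",
    dates = eln_date_set(as.Date("2013-08-01"),
                         releaseDate = as.Date("2014-02-01"),
                         publicationDate = as.Date("2014-05-10"),
                         submissionDate = as.Date("2013-12-01")),
    relatedItems = list(eln_related_item("publication", "10.1186/1758-2946-5-52"),
                        eln_related_item("related work", "EXP-1001")),
    content = list(eln_content_item("Record body", "text/html"),
                   eln_content_item("Structure file", "chemical/x-mdl-sdfile",
                                    "http://data.example.org/eln/1042/s.sdf")))
}

# independent calendar oracle: month length via "first of next month minus
# one day", distinct from the implementation's leap-rule month table
oracle_release_date <- function(base, years, months, weeks, days) {
  lt <- as.POSIXlt(base)
  ym <- (lt$year + 1900L) * 12L + lt$mon + years * 12L + months
  yy <- ym %/% 12L
  mm <- ym %% 12L + 1L
  next_first <- if (mm == 12L) as.Date(sprintf("%d-01-01", yy + 1L)) else
    as.Date(sprintf("%d-%02d-01", yy, mm + 1L))
  d <- min(lt$mday, as.integer(format(next_first - 1L, "%d")))
  as.Date(sprintf("%d-%02d-%02d", yy, mm, d)) + weeks * 7L + days
}

# naive feed oracle: unpaged one-by-one scan in (lastModified, storeId) order
naive_scan <- function(store, filter, today) {
  entries <- store$entries
  if (!is.null(filter$modifiedSince))
    entries <- Filter(function(e) e$lastModified >= filter$modifiedSince,
                      entries)
  keep <- Filter(function(e) manifest_matches(e$manifest, filter, today),
                 entries)
  if (!length(keep)) return(character())
  ids <- vapply(keep, `[[`, character(1), "storeId")
  stamps <- vapply(keep, function(e)
    format(e$lastModified, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), character(1))
  ids[order(stamps, ids)]
}

# deterministic random filter specs for oracle-equivalence sweeps
random_filter <- function(i, today) {
  set.seed(90000L + i)
  maybe <- function(p, x) if (runif(1) < p) x else NULL
  filter_spec(
    unitTypes = maybe(0.4, sample(eln_unit_types(),
                                  sample(1:2, 1))),
    mediaTypes = maybe(0.5, sample(c("chemical/x-mdl-sdfile", "chemical/x-cml",
                                     "image/png", "text/csv", "text/html",
                                     "application/pdf"), sample(1:3, 1))),
    keywordsAny = maybe(0.3, sample(c("oxindole", "NMR", "yield", "oxime"),
                                    sample(1:2, 1))),
    requireReleased = runif(1) < 0.5,
    licensePrefix = maybe(0.3, sample(c("CC-BY", "cc0", "CC"), 1)),
    modifiedSince = maybe(0.3, as.POSIXct(today - sample(50:700, 1),
                                          tz = "UTC")))
}
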