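# Deterministic synthetic fixtures: source ELN records in the two styles the
# demonstrators cover (blog-style records with permalink URLs, experiment-
# database records with experiment ids), full manifests exercising every
# optional field, V2000 molfiles, and whole manifest stores. Generation is
# counter-based — every drawn value is a pure function of (seed, index,
# fieldName) — so any record can be regenerated independently of order,
# wall clock or locale.

FIXTURE_MEDIA_PALETTE <- c("chemical/x-mdl-sdfile", "chemical/x-cml",
                           "image/png", "text/csv", "application/pdf")

FIXTURE_EXTENSIONS <- c("chemical/x-mdl-sdfile" = "sdf",
                        "chemical/x-cml" = "cml",
                        "image/png" = "png",
                        "text/csv" = "csv",
                        "application/pdf" = "pdf")

FIXTURE_SUBSTANCES <- c("bromophenyl oxindole", "methyl oxime",
                        "dihydroindolone", "benzaldehyde hydrazone",
                        "nitrostyrene adduct", "pyridyl ketone",
                        "chloroaniline amide", "furyl acrylate")
FIXTURE_ACTIVITIES <- c("Synthesis", "Spectrum", "Crystallisation",
                        "Kinetics", "Workup", "Titration")
FIXTURE_SURNAMES <- c("Bird", "Coles", "Frey", "Willoughby", "Day", "Hughes",
                      "Milsted", "Whitby")
FIXTURE_KEYWORDS <- c("oxindole", "NMR", "bromination", "yield",
                      "crystallography", "oxime", "catalysis", "IR")
FIXTURE_EMBARGOES <- c("P1M", "P6M", "P1Y", "P14D")
FIXTURE_LICENSES <- c("CC-BY-4.0", "CC-BY-SA-4.0", "CC0-1.0")

# counter-based uniform deviate in [0,1): pure in (seed, index, field)
det_unit <- function(seed, index, field) {
  fnv1a(sprintf("%d|%d|%s", as.integer(seed), as.integer(index), field)) /
    4294967296
}

det_pick <- function(seed, index, field, choices) {
  choices[[1L + floor(det_unit(seed, index, field) * length(choices))]]
}

det_int <- function(seed, index, field, lo, hi) {
  lo + floor(det_unit(seed, index, field) * (hi - lo + 1L))
}

#' A fixture generation profile
#'
#' Controls the synthetic record population: how many records, how often
#' each media type from the palette is attached, how often depositions carry
#' an embargo or a related publication, and the creation-date window.
#' Defaults describe a mid-size open-notebook project: fifty records over
#' two years, roughly one attachment of each common type every two to three
#' records, embargoes on about a third of depositions and a linked
#' publication DOI on forty percent.
#'
#' @param seed Integer seed; all generated content is a pure function of it.
#' @param nRecords Number of records in the population.
#' @param attachmentRate Named numeric vector of per-record attachment
#'   probabilities, one per media type.
#' @param embargoRate Probability a deposition carries a nonzero embargo.
#' @param publicationRate Probability a record links a publication DOI.
#' @param dateRange Length-2 vector of dates bounding creation dates.
#' @return An object of class \code{eln_fixture_profile}.
#' @export
fixture_profile <- function(seed = 1L, nRecords = 50L,
                            attachmentRate = c("chemical/x-mdl-sdfile" = 0.4,
                                               "chemical/x-cml" = 0.3,
                                               "image/png" = 0.5,
                                               "text/csv" = 0.35,
                                               "application/pdf" = 0.25),
                            embargoRate = 0.3, publicationRate = 0.4,
                            dateRange = as.Date(c("2012-01-01", "2013-12-31"))) {
  if (any(attachmentRate < 0 | attachmentRate > 1) ||
      embargoRate < 0 || embargoRate > 1 ||
      publicationRate < 0 || publicationRate > 1)
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  dateRange <- as.Date(dateRange)
  if (dateRange[1] > dateRange[2])
    stop("dateRange start must not exceed its end", call. = FALSE)
  structure(list(seed = as.integer(seed), nRecords = as.integer(nRecords),
                 attachmentRate = attachmentRate, embargoRate = embargoRate,
                 publicationRate = publicationRate, dateRange = dateRange),
            class = "eln_fixture_profile")
}

fixture_title <- function(seed, index) {
  paste(det_pick(seed, index, "activity", FIXTURE_ACTIVITIES), "of",
        det_pick(seed, index, "substance", FIXTURE_SUBSTANCES))
}

fixture_date <- function(seed, index, profile, field = "createdOn") {
  span <- as.integer(profile$dateRange[2] - profile$dateRange[1])
  profile$dateRange[1] + det_int(seed, index, field, 0L, span)
}

fixture_authors <- function(seed, index) {
  n <- det_int(seed, index, "nAuthors", 1L, 3L)
  lapply(seq_len(n), function(j) {
    role <- if (j == 1L) "Author" else
      det_pick(seed, index, paste0("authorRole", j), c("Author", "PI"))
    initial <- LETTERS[det_int(seed, index, paste0("authorInitial", j), 1L, 26L)]
    surname <- det_pick(seed, index, paste0("authorName", j), FIXTURE_SURNAMES)
    c(role, sprintf("%s. %s", initial, surname))
  })
}

#' Generate one synthetic source ELN record
#'
#' Records alternate between the two source styles: even indices are
#' blog-style (permalink-URL identifier, HTML body), odd indices are
#' experiment-database style (experiment-id identifier, XHTML body).
#' Identical \code{(seed, index)} always yields an identical record.
#'
#' @param profile An \code{\link{fixture_profile}}.
#' @param index Record index in \code{0:(nRecords - 1)}.
#' @return An \code{\link{eln_record_source}}.
#' @export
generate_record <- function(profile, index) {
  if (!inherits(profile, "eln_fixture_profile"))
    stop("generate_record() expects an eln_fixture_profile", call. = FALSE)
  if (index < 0 || index >= profile$nRecords)
    stop(sprintf("index %d outside 0:%d", index, profile$nRecords - 1L),
         call. = FALSE)
  seed <- profile$seed
  title <- fixture_title(seed, index)
  slug <- gsub(" ", "_", title)
  blog_style <- index %% 2L == 0L
  localId <- if (blog_style) {
    sprintf("http://eln.example.org/notebook/%d/%s.html", 5000L + index, slug)
  } else {
    sprintf("EXP-%04d", 1000L + index)
  }
  attachments <- list()
  for (mt in names(profile$attachmentRate)) {
    if (det_unit(seed, index, paste0("attach|", mt)) <
        profile$attachmentRate[[mt]]) {
      ext <- FIXTURE_EXTENSIONS[[mt]] %||% "dat"
      fn <- sprintf("item%03d.%s", length(attachments) + 1L, ext)
      loc <- NULL
      if (det_unit(seed, index, paste0("attachLoc|", mt)) < 0.5)
        loc <- sprintf("http://eln.example.org/files/%d/%s", 5000L + index, fn)
      attachments[[length(attachments) + 1L]] <-
        list(filename = fn, mediaType = mt,
             description = sprintf("%s attachment (%s)", mt, fn),
             locator = loc)
    }
  }
  related <- list()
  if (det_unit(seed, index, "publication") < profile$publicationRate)
    related[[1L]] <- c("publication",
                       sprintf("10.1186/eln-fixture-%d-%d", seed, index))
  if (det_unit(seed, index, "relatedWork") < 0.2)
    related[[length(related) + 1L]] <-
      c("related work", sprintf("EXP-%04d", det_int(seed, index, "relatedId",
                                                    1000L, 1999L)))
  eln_record_source(
    localId = localId, title = title, authors = fixture_authors(seed, index),
    createdOn = fixture_date(seed, index, profile),
    systemName = if (blog_style) "OpenBlogELN" else "ExperimentDB",
    systemVersion = if (blog_style) "2.3" else "9.2.0",
    attachments = attachments, relatedPublications = related,
    bodyMediaType = if (blog_style) "text/html" else "application/xhtml+xml")
}

#' Generate the per-deposition user input for one record
#'
#' Draws the licensing basis and embargo the depositing user would enter:
#' an embargo with probability \code{embargoRate}, a license with
#' probability 0.7.
#'
#' @param profile An \code{\link{fixture_profile}}.
#' @param index Record index.
#' @return An \code{\link{eln_user_input}}.
#' @export
generate_user_input <- function(profile, index) {
  seed <- profile$seed
  embargo <- NULL
  if (det_unit(seed, index, "embargo") < profile$embargoRate)
    embargo <- det_pick(seed, index, "embargoLen", FIXTURE_EMBARGOES)
  license <- NULL
  if (det_unit(seed, index, "license") < 0.7)
    license <- det_pick(seed, index, "licenseName", FIXTURE_LICENSES)
  eln_user_input(licensingBasis = license, embargo = embargo)
}

#' Default site configuration used by the fixture store
#'
#' @return An \code{\link{eln_site_config}} with an e-mail contact and two
#'   standing contributors (a PI and the hosting institution).
#' @export
fixture_site_config <- function() {
  eln_site_config(
    eln_contact("EMail", "eln-curator@example.org"),
    list(eln_contributor("PI", "F. Willoughby",
                         "https://orcid.org/0000-0002-0000-0001"),
         eln_contributor("Institution", "Example University")))
}

#' Generate a store of derived manifests
#'
#' Runs \code{\link{derive_manifest}} over the whole synthetic record
#' population, pairing each record with its generated user input. Every
#' resulting manifest validates with zero errors.
#'
#' @param profile An \code{\link{fixture_profile}}.
#' @param config An \code{\link{eln_site_config}}; defaults to
#'   \code{\link{fixture_site_config}()}.
#' @return An \code{eln_manifest_store} of \code{nRecords} entries with
#'   store ids \code{rec-0000, rec-0001, ...} and lastModified stamps at
#'   noon UTC of each record's creation date.
#' @export
generate_store <- function(profile, config = fixture_site_config()) {
  store <- manifest_store()
  for (index in seq_len(profile$nRecords) - 1L) {
    src <- generate_record(profile, index)
    m <- derive_manifest(src, config, generate_user_input(profile, index))
    store <- store_add(store, m, sprintf("rec-%04d", index),
                       as.POSIXct(paste(src$createdOn, "12:00:00"), tz = "UTC"))
  }
  store
}

#' Generate a full-coverage manifest directly
#'
#' Unlike \code{\link{generate_store}}, which only produces what derivation
#' from a source record can produce, this draws a manifest over the entire
#' schema — keywords, other local identifiers, access identifier,
#' publication and submission dates included — for property tests of
#' serialization, crosswalk and tier resolution.
#'
#' @param profile An \code{\link{fixture_profile}}.
#' @param index Manifest index.
#' @return A valid \code{\link{eln_manifest}}.
#' @export
generate_manifest <- function(profile, index) {
  seed <- profile$seed
  src <- generate_record(profile, index)
  user <- generate_user_input(profile, index)
  m <- derive_manifest(src, fixture_site_config(), user,
                       unitType = det_pick(seed, index, "unitType",
                                           eln_unit_types()))
  args <- unclass(m)
  if (det_unit(seed, index, "hasKeywords") < 0.8) {
    n <- det_int(seed, index, "nKeywords", 1L, 4L)
    args$keywords <- unique(vapply(seq_len(n), function(j)
      det_pick(seed, index, paste0("keyword", j), FIXTURE_KEYWORDS),
      character(1)))
  }
  other <- NULL
  if (det_unit(seed, index, "hasOtherId") < 0.5)
    other <- sprintf("hdl:20.1000/eln-%d-%d", seed, index)
  access <- NULL
  if (det_unit(seed, index, "hasAccessId") < 0.5)
    access <- sprintf("http://data.example.org/eln/%d/%d", seed, index)
  args$identifiers <- eln_identifier_set(
    args$identifiers$primaryLocalIdentifier, other %||% character(), access)
  dates <- args$dates
  if (det_unit(seed, index, "hasPubDate") < 0.4)
    dates$publicationDate <- dates$creationDate +
      det_int(seed, index, "pubLag", 30L, 400L)
  if (det_unit(seed, index, "hasSubDate") < 0.4)
    dates$submissionDate <- dates$creationDate +
      det_int(seed, index, "subLag", 10L, 200L)
  args$dates <- eln_date_set(dates$creationDate, dates$releaseDate,
                             dates$publicationDate, dates$submissionDate)
  do.call(eln_manifest, args[!vapply(args, is.null, logical(1))])
}

#' Generate a syntactically valid V2000 molfile
#'
#' A chain of C/N/O atoms laid out on a planar grid with single bonds: not
#' chemically meaningful, but a well-formed molfile that any V2000 reader
#' parses (header, counts line, atom block, bond block, \code{M  END}).
#'
#' @param seed Integer seed.
#' @param nAtoms Number of atoms, between 1 and 99.
#' @return Single character string: the molfile text, newline-terminated.
#' @export
generate_molfile <- function(seed, nAtoms) {
  if (!is.numeric(nAtoms) || nAtoms < 1 || nAtoms > 99)
    stop("nAtoms must be between 1 and 99", call. = FALSE)
  nAtoms <- as.integer(nAtoms)
  nBonds <- nAtoms - 1L
  atoms <- vapply(seq_len(nAtoms), function(i) {
    el <- det_pick(seed, i, "element", c("C", "C", "C", "N", "O"))
    x <- ((i - 1L) %% 10L) * 1.5
    y <- ((i - 1L) %/% 10L) * 1.5
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            x, y, 0, el)
  }, character(1))
  bonds <- if (nBonds > 0L) {
    vapply(seq_len(nBonds), function(i)
      sprintf("%3d%3d%3d%3d", i, i + 1L, 1L, 0L), character(1))
  } else character()
  paste0(paste(c(sprintf("FIX-%d-%d", as.integer(seed), nAtoms),
                 "  elnmanifest fixture", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nAtoms, nBonds),
                 atoms, bonds, "M  END"), collapse = "\n"), "\n")
}

#' Write a fixture corpus to a directory
#'
#' Materialises \code{nRecords} source-record JSON files, the derived
#' manifest XML documents, and one molfile per record.
#'
#' @param profile An \code{\link{fixture_profile}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture_corpus <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- fixture_site_config()
  for (index in seq_len(profile$nRecords) - 1L) {
    src <- generate_record(profile, index)
    write_record_json(src, file.path(dir, sprintf("record-%04d.json", index)))
    m <- derive_manifest(src, config, generate_user_input(profile, index))
    write_manifest(m, file.path(dir, sprintf("manifest-%04d.xml", index)))
    nAtoms <- det_int(profile$seed, index, "molAtoms", 2L, 20L)
    cat(generate_molfile(profile$seed + index, nAtoms),
        file = file.path(dir, sprintf("structure-%04d.mol", index)))
  }
  invisible(dir)
}
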