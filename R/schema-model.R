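# In-memory model of the elnItemManifest: a compact knowledge-layer metadata
# record describing one unit held in an Electronic Laboratory Notebook (a
# package of records, a single record, or a component such as a spectrum).
# Constructors enforce the structural invariants so that a constructed
# manifest always passes semantic validation with zero errors.

#' Unit types an ELN manifest may describe
#'
#' The closed set of values for the \code{unitType} qualifier of a manifest:
#' \code{"Package"} (multiple ELN records), \code{"Record"} (an individual
#' record) or \code{"Component"} (a part of a record, such as a spectrum or
#' a reaction).
#'
#' @return Character vector of the three permitted unit types.
#' @export
#' @examples
#' eln_unit_types()
eln_unit_types <- function() c("Package", "Record", "Component")

#' Contact modes for the manifest Contact element
#'
#' @return Character vector of the three permitted contact modes:
#'   \code{"EMail"}, \code{"SystemURI"} or \code{"Instruction"}.
#' @export
eln_contact_modes <- function() c("EMail", "SystemURI", "Instruction")

# ---- low-level syntactic checks ---------------------------------------------

is_nonempty_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(trimws(x))
}

#' @keywords internal
is_absolute_uri <- function(x) {
  # scheme ":" hier-part, no whitespace; syntactic only, never dereferenced
  is_nonempty_string(x) && grepl("^[A-Za-z][A-Za-z0-9+.-]*:[^[:space:]]+$", x)
}

#' @keywords internal
is_email_address <- function(x) {
  # addr-spec shape only: exactly one "@", non-empty local and domain parts
  is_nonempty_string(x) && grepl("^[^@[:space:]]+@[^@[:space:]]+$", x)
}

#' @keywords internal
is_media_type <- function(x) {
  # IANA "type/subtype" syntax, e.g. "chemical/x-mdl-sdfile"
  is_nonempty_string(x) &&
    grepl("^[A-Za-z0-9][A-Za-z0-9!#$&^_.+-]*/[A-Za-z0-9][A-Za-z0-9!#$&^_.+-]*$", x)
}

stop_eln <- function(path, fmt, ...) {
  stop(sprintf("[%s] %s", path, sprintf(fmt, ...)), call. = FALSE)
}

as_eln_date <- function(x, path) {
  if (inherits(x, "Date")) {
    if (length(x) != 1L || is.na(x)) stop_eln(path, "must be a single calendar date")
    return(x)
  }
  if (is_nonempty_string(x)) {
    d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
    if (!is.na(d) && format(d, "%Y-%m-%d") == x) return(d)
  }
  stop_eln(path, "must be an ISO 8601 calendar date (YYYY-MM-DD), got %s",
           deparse(substitute(x)))
}

# ---- component constructors -------------------------------------------------

#' Identifier set for a manifest
#'
#' Unique handles locating the described ELN unit.
#'
#' @param primaryLocalIdentifier Non-empty string (URI or any other format)
#'   that locates the record uniquely in the originating system.
#' @param otherLocalIdentifiers Optional character vector of alternative
#'   local identifiers; must not repeat the primary identifier.
#' @param accessIdentifier Optional absolute (linked-data) URI giving direct
#'   open access to the content.
#' @return An object of class \code{eln_identifier_set}.
#' @export
#' @examples
#' eln_identifier_set("EXP-2013-0042",
#'                    accessIdentifier = "https://eln.example.org/EXP-2013-0042")
eln_identifier_set <- function(primaryLocalIdentifier,
                               otherLocalIdentifiers = character(),
                               accessIdentifier = NULL) {
  if (!is_nonempty_string(primaryLocalIdentifier))
    stop_eln("Identifiers/PrimaryLocalIdentifier", "must be a non-empty string")
  other <- as.character(otherLocalIdentifiers %||% character())
  if (any(!nzchar(other)))
    stop_eln("Identifiers/OtherLocalIdentifier", "entries must be non-empty")
  if (primaryLocalIdentifier %in% other)
    stop_eln("Identifiers/OtherLocalIdentifier",
             "must not duplicate the primary local identifier")
  if (!is.null(accessIdentifier) && !is_absolute_uri(accessIdentifier))
    stop_eln("Identifiers/AccessIdentifier", "must be an absolute URI")
  structure(list(primaryLocalIdentifier = primaryLocalIdentifier,
                 otherLocalIdentifiers = other,
                 accessIdentifier = accessIdentifier),
            class = "eln_identifier_set")
}

#' Contact option for a manifest
#'
#' Who or what to contact for more information about the record: an e-mail
#' address, a system URI, or a brief free-text instruction.
#'
#' @param mode One of \code{eln_contact_modes()}.
#' @param value Non-empty string; for \code{EMail} it must look like an
#'   address (one \code{@} with non-empty parts), for \code{SystemURI} it
#'   must be an absolute URI.
#' @return An object of class \code{eln_contact}.
#' @export
eln_contact <- function(mode, value) {
  if (!is_nonempty_string(mode) || !mode %in% eln_contact_modes())
    stop_eln("Contact", "mode must be one of: %s",
             paste(eln_contact_modes(), collapse = ", "))
  if (!is_nonempty_string(value))
    stop_eln("Contact", "value must be a non-empty string")
  if (mode == "EMail" && !is_email_address(value))
    stop_eln("Contact", "value %s is not a valid e-mail address", dQuote(value))
  if (mode == "SystemURI" && !is_absolute_uri(value))
    stop_eln("Contact", "value %s is not an absolute URI", dQuote(value))
  structure(list(mode = mode, value = value), class = "eln_contact")
}

#' Contributor entry for a manifest
#'
#' @param role Free-text role, e.g. \code{"Author"}, \code{"PI"},
#'   \code{"Funding Body"}, \code{"Institution"}. No controlled vocabulary is
#'   imposed; unrecognised roles only draw a validation warning.
#' @param name Non-empty person or organisation name.
#' @param identifiers Optional character vector of unique identifiers (e.g.
#'   ORCID) complementing the name.
#' @return An object of class \code{eln_contributor}.
#' @export
eln_contributor <- function(role, name, identifiers = NULL) {
  if (!is_nonempty_string(role))
    stop_eln("Contributors/Role", "must be a non-empty string")
  if (!is_nonempty_string(name))
    stop_eln("Contributors/Name", "must be a non-empty string")
  if (!is.null(identifiers)) {
    identifiers <- as.character(identifiers)
    if (any(!nzchar(identifiers)))
      stop_eln("Contributors/Identifier", "entries must be non-empty")
    if (length(identifiers) == 0L) identifiers <- NULL
  }
  structure(list(role = role, name = name, identifiers = identifiers),
            class = "eln_contributor")
}

#' Date set for a manifest
#'
#' @param creationDate Mandatory date the record was created.
#' @param releaseDate Optional date any embargo ends; must not precede the
#'   creation date.
#' @param publicationDate,submissionDate Optional dates for an associated
#'   publication or a submission to a conference or journal.
#' @return An object of class \code{eln_date_set}.
#' @export
eln_date_set <- function(creationDate, releaseDate = NULL,
                         publicationDate = NULL, submissionDate = NULL) {
  creationDate <- as_eln_date(creationDate, "Date/CreationDate")
  if (!is.null(releaseDate)) {
    releaseDate <- as_eln_date(releaseDate, "Date/ReleaseDate")
    if (releaseDate < creationDate)
      stop_eln("Date/ReleaseDate", "must not precede the creation date")
  }
  if (!is.null(publicationDate))
    publicationDate <- as_eln_date(publicationDate, "Date/PublicationDate")
  if (!is.null(submissionDate))
    submissionDate <- as_eln_date(submissionDate, "Date/SubmissionDate")
  structure(list(creationDate = creationDate, releaseDate = releaseDate,
                 publicationDate = publicationDate,
                 submissionDate = submissionDate),
            class = "eln_date_set")
}

#' Related item entry
#'
#' @param relationship Nature of the relation (e.g. \code{"publication"},
#'   \code{"related work"}).
#' @param id Identifier of the related item; any string, but a DOI is
#'   preferred when the item is a publication.
#' @return An object of class \code{eln_related_item}.
#' @export
eln_related_item <- function(relationship, id) {
  if (!is_nonempty_string(relationship))
    stop_eln("RelatedItems/Relationship", "must be a non-empty string")
  if (!is_nonempty_string(id))
    stop_eln("RelatedItems/Id", "must be a non-empty string")
  structure(list(relationship = relationship, id = id),
            class = "eln_related_item")
}

#' Content item entry
#'
#' One item comprising the described record: a human-readable description,
#' its media type, and optionally a locator giving processing-layer access.
#'
#' @param description Non-empty human-readable description of the item.
#' @param dataType Media type in IANA \code{type/subtype} syntax.
#' @param locator Optional URI locating the item itself.
#' @return An object of class \code{eln_content_item}.
#' @export
eln_content_item <- function(description, dataType, locator = NULL) {
  if (!is_nonempty_string(description))
    stop_eln("Content/ContentItem/Description", "must be a non-empty string")
  if (!is_media_type(dataType))
    stop_eln("Content/ContentItem/DataType",
             "%s is not in type/subtype media-type syntax", dQuote(dataType))
  if (!is.null(locator) && !is_absolute_uri(locator))
    stop_eln("Content/ContentItem/Locator", "must be an absolute URI")
  structure(list(description = description, dataType = dataType,
                 locator = locator),
            class = "eln_content_item")
}

as_item_list <- function(x, cls, path) {
  if (inherits(x, cls)) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), cls)))
    stop_eln(path, "must be a list of %s objects", cls)
  names(x) <- NULL
  x
}

# ---- the manifest itself ----------------------------------------------------

#' Build an ELN item manifest
#'
#' Constructs the full knowledge-layer metadata record for one ELN unit.
#' The mandatory parts are the unit type, title, identifiers, contact,
#' contributors, source, dates and content; keywords, licensing basis and
#' related items may be omitted. Construction fails, naming the offending
#' element, when a mandatory field is missing or an invariant is violated.
#'
#' @param unitType One of \code{eln_unit_types()}: \code{"Package"},
#'   \code{"Record"} or \code{"Component"}.
#' @param title Short, human-readable title; leading/trailing whitespace is
#'   trimmed.
#' @param identifiers An \code{\link{eln_identifier_set}}, or a single string
#'   used as the primary local identifier.
#' @param contact An \code{\link{eln_contact}}.
#' @param contributors A non-empty list of \code{\link{eln_contributor}}
#'   objects (a single contributor may be given unwrapped).
#' @param source Non-empty string describing the generating system, typically
#'   vendor, software package and version (resembles a browser user agent).
#' @param dates An \code{\link{eln_date_set}}, or a single creation date.
#' @param content Non-empty list of \code{\link{eln_content_item}} objects.
#' @param keywords Optional character vector of search/categorisation terms;
#'   trimmed, empties dropped, and deduplicated case-sensitively.
#' @param licensingBasis Optional licensing indication, e.g. a Creative
#'   Commons license name.
#' @param relatedItems Optional list of \code{\link{eln_related_item}}
#'   objects.
#' @return An object of class \code{eln_manifest}.
#' @seealso \code{\link{manifest_to_xml}}, \code{\link{validate_manifest}},
#'   \code{\link{derive_manifest}}
#' @export
#' @examples
#' m <- eln_manifest(
#'   unitType = "Record",
#'   title = "Spectrum of 3-(1-bromophenyl)-1,3-dihydroindol-2H-one",
#'   identifiers = "http://eln.example.org/synth/5606/spectrum.html",
#'   contact = eln_contact("EMail", "curator@example.org"),
#'   contributors = eln_contributor("Author", "A. Chemist"),
#'   source = "LabTrove/2.3",
#'   dates = eln_date_set(as.Date("2013-08-01")),
#'   content = eln_content_item("Record body", "text/html"))
#' m$unitType
eln_manifest <- function(unitType, title, identifiers, contact, contributors,
                         source, dates, content,
                         keywords = NULL, licensingBasis = NULL,
                         relatedItems = NULL) {
  for (f in c("unitType", "title", "identifiers", "contact", "contributors",
              "source", "dates", "content")) {
    if (eval(call("missing", as.name(f))) || is.null(get(f)))
      stop_eln(f, "mandatory field is missing")
  }
  if (!is_nonempty_string(unitType) || !unitType %in% eln_unit_types())
    stop_eln("unitType", "must be one of: %s (got %s)",
             paste(eln_unit_types(), collapse = ", "),
             dQuote(as.character(unitType)[1]))
  if (!is_nonempty_string(title)) stop_eln("Title", "must be a non-empty string")
  title <- trimws(title)
  if (is.character(identifiers)) identifiers <- eln_identifier_set(identifiers)
  if (!inherits(identifiers, "eln_identifier_set"))
    stop_eln("Identifiers", "must be an eln_identifier_set")
  if (!inherits(contact, "eln_contact"))
    stop_eln("Contact", "must be an eln_contact")
  contributors <- as_item_list(contributors, "eln_contributor", "Contributors")
  if (length(contributors) == 0L)
    stop_eln("Contributors", "at least one contributor is required")
  if (!is_nonempty_string(source))
    stop_eln("Source", "must be a non-empty string")
  if (inherits(dates, "Date") || is.character(dates)) dates <- eln_date_set(dates)
  if (!inherits(dates, "eln_date_set"))
    stop_eln("Date", "must be an eln_date_set")
  content <- as_item_list(content, "eln_content_item", "Content")
  if (length(content) == 0L)
    stop_eln("Content", "at least one content item is required")
  if (!is.null(keywords)) {
    keywords <- unique(trimws(as.character(keywords)))
    keywords <- keywords[nzchar(keywords)]
    if (length(keywords) == 0L) keywords <- NULL
  }
  if (!is.null(licensingBasis) && !is_nonempty_string(licensingBasis))
    stop_eln("LicensingBasis", "when given, must be a non-empty string")
  if (!is.null(relatedItems)) {
    relatedItems <- as_item_list(relatedItems, "eln_related_item", "RelatedItems")
    if (length(relatedItems) == 0L) relatedItems <- NULL
  }
  structure(list(unitType = unitType, title = title, keywords = keywords,
                 identifiers = identifiers, contact = contact,
                 licensingBasis = licensingBasis, contributors = contributors,
                 source = source, dates = dates, relatedItems = relatedItems,
                 content = content),
            class = "eln_manifest")
}

#' @export
print.eln_manifest <- function(x, ...) {
  cat(sprintf("<elnItemManifest unitType=%s>\n", dQuote(x$unitType)))
  cat("  Title:      ", x$title, "\n", sep = "")
  cat("  Identifier: ", x$identifiers$primaryLocalIdentifier, "\n", sep = "")
  if (!is.null(x$identifiers$accessIdentifier))
    cat("  Access:     ", x$identifiers$accessIdentifier, "\n", sep = "")
  cat("  Contact:    ", x$contact$mode, ": ", x$contact$value, "\n", sep = "")
  cat("  Source:     ", x$source, "\n", sep = "")
  cat("  Created:    ", format(x$dates$creationDate), "\n", sep = "")
  if (!is.null(x$dates$releaseDate))
    cat("  Released:   ", format(x$dates$releaseDate), "\n", sep = "")
  if (!is.null(x$licensingBasis))
    cat("  License:    ", x$licensingBasis, "\n", sep = "")
  if (!is.null(x$keywords))
    cat("  Keywords:   ", paste(x$keywords, collapse = ", "), "\n", sep = "")
  cat(sprintf("  Contributors (%d): %s\n", length(x$contributors),
              paste(vapply(x$contributors,
                           function(co) sprintf("%s (%s)", co$name, co$role),
                           character(1)), collapse = "; ")))
  if (!is.null(x$relatedItems))
    cat(sprintf("  Related items: %d\n", length(x$relatedItems)))
  cat(sprintf("  Content items (%d): %s\n", length(x$content),
              paste(vapply(x$content, `[[`, character(1), "dataType"),
                    collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- embargo arithmetic -----------------------------------------------------

#' Parse an ISO 8601 calendar duration
#'
#' Accepts date-level designators only (years, months, weeks, days), e.g.
#' \code{"P6M"}, \code{"P1Y2M"}, \code{"P14D"}. Time-of-day components and
#' negative durations are rejected: embargo periods are whole calendar days.
#'
#' @param x Duration string.
#' @return Named integer vector with components \code{years}, \code{months},
#'   \code{weeks}, \code{days}.
#' @export
#' @examples
#' parse_iso_duration("P1Y6M")
parse_iso_duration <- function(x) {
  if (!is_nonempty_string(x))
    stop("duration must be a non-empty ISO 8601 string", call. = FALSE)
  if (grepl("^-|^P.*-", x))
    stop(sprintf("negative duration %s is not a valid embargo period",
                 dQuote(x)), call. = FALSE)
  m <- regmatches(x, regexec(
    "^P(?:([0-9]+)Y)?(?:([0-9]+)M)?(?:([0-9]+)W)?(?:([0-9]+)D)?$", x))[[1]]
  if (length(m) == 0L || all(m[-1] == ""))
    stop(sprintf("cannot parse %s as an ISO 8601 date duration", dQuote(x)),
         call. = FALSE)
  vals <- suppressWarnings(as.integer(m[-1]))
  vals[is.na(vals)] <- 0L
  names(vals) <- c("years", "months", "weeks", "days")
  vals
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  n + as.integer(month == 2L & leap)
}

#' Compute a release date from a creation date and an embargo period
#'
#' Advances \code{base} by an ISO 8601 calendar duration. Year/month
#' arithmetic clamps to the last valid day of the target month (so one month
#' after 31 January is 28 or 29 February), then whole weeks and days are
#' added. This is how a manifest's \code{releaseDate} is calculated from the
#' user-entered embargo period at deposition time.
#'
#' @param base Calendar date the embargo starts from (the creation date).
#' @param embargo ISO 8601 duration string, e.g. \code{"P6M"}; must be
#'   non-negative.
#' @return A \code{Date}.
#' @export
#' @examples
#' compute_release_date(as.Date("2013-08-31"), "P6M")  # clamps to 2014-02-28
compute_release_date <- function(base, embargo) {
  base <- as_eln_date(base, "Date/CreationDate")
  d <- parse_iso_duration(embargo)
  lt <- as.POSIXlt(base)
  year <- lt$year + 1900L
  month <- lt$mon + 1L
  day <- lt$mday
  total <- (year * 12L + (month - 1L)) + d[["years"]] * 12L + d[["months"]]
  year <- total %/% 12L
  month <- total %% 12L + 1L
  day <- min(day, days_in_month(year, month))
  out <- as.Date(sprintf("%04d-%02d-%02d", year, month, day))
  out + d[["weeks"]] * 7L + d[["days"]]
}
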