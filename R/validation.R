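# Rule-based semantic validation beyond XML well-formedness. All problems
# are reported, never thrown: the report lists every violation with a rule
# id, a severity and the element path, and a manifest is valid iff no
# violation has severity "error".

ELN_MANDATORY_PARTS <- c("unitType", "Title", "Identifiers", "Contact",
                         "Contributors", "Source", "Date", "Content")

# roles listed as examples in the schema; anything else is free text and
# only draws a warning
ELN_KNOWN_ROLES <- c("author", "pi", "principal investigator", "funding body",
                     "institution", "contributor", "curator")

#' The validation rule catalogue
#'
#' @return Data frame with one row per rule: \code{ruleId}, default
#'   \code{severity} and a short description.
#' @export
eln_rule_catalogue <- function() {
  data.frame(
    ruleId = c("MANDATORY_MISSING", "EMPTY_VALUE", "UNIT_TYPE_INVALID",
               "CONTACT_MODE_INVALID", "CONTACT_VALUE_INVALID",
               "ACCESS_IDENTIFIER_NOT_URI", "DATE_ORDER_INVALID",
               "DATE_SYNTAX_INVALID", "DATA_TYPE_SYNTAX",
               "LOCATOR_NOT_URI", "IDENTIFIER_DUPLICATE",
               "RELATED_ITEM_DOI_PREFERRED", "KEYWORDS_EMPTY",
               "ROLE_UNRECOGNIZED"),
    severity = c("error", "error", "error", "error", "error", "error",
                 "error", "error", "error", "error", "error",
                 "warning", "warning", "warning"),
    description = c(
      "a mandatory element or attribute is absent",
      "a mandatory text value is empty",
      "unitType is not Package, Record or Component",
      "Contact mode is not EMail, SystemURI or Instruction",
      "Contact value does not fit the declared mode",
      "AccessIdentifier is not an absolute URI",
      "ReleaseDate precedes CreationDate",
      "a date is not an ISO 8601 calendar date",
      "DataType is not in type/subtype media-type syntax",
      "a Locator is not an absolute URI",
      "OtherLocalIdentifier duplicates the primary identifier",
      "related item looks like a publication but its id is not a DOI",
      "Keywords element present but holds no usable terms",
      "contributor role outside the customary set"),
    stringsAsFactors = FALSE)
}

new_report <- function(violations) {
  if (length(violations) == 0L) {
    df <- data.frame(ruleId = character(), severity = character(),
                     path = character(), message = character(),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(violations, as.data.frame,
                                stringsAsFactors = FALSE))
  }
  structure(list(violations = df, valid = !any(df$severity == "error")),
            class = "eln_validation_report")
}

violation <- function(ruleId, severity, path, message) {
  list(ruleId = ruleId, severity = severity, path = path, message = message)
}

#' Whether a string is a recognisable DOI
#'
#' Accepts bare (\code{10.x/y}), \code{doi:}-prefixed and
#' \code{https://doi.org/} forms.
#'
#' @param x Character string.
#' @return Logical scalar.
#' @export
is_doi <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) return(FALSE)
  bare <- sub("^doi:", "", sub("^https?://(dx\\.)?doi\\.org/", "", x,
                               ignore.case = TRUE), ignore.case = TRUE)
  grepl("^10\\.[0-9]{2,}(\\.[0-9]+)*/\\S+$", bare)
}

#' Validate a manifest or manifest document
#'
#' Applies the semantic rule catalogue (\code{\link{eln_rule_catalogue}}) to
#' either an in-memory \code{\link{eln_manifest}} or a well-formed XML
#' document in the manifest dialect. Nothing is thrown: every problem is a
#' row of the returned report. Missing mandatory parts, a unit type outside
#' the closed set, contact values that do not fit their mode, a non-URI
#' access identifier, a release date before the creation date and malformed
#' media types are errors; a publication-related item without a DOI, an
#' empty keyword set and unrecognised contributor roles are warnings.
#'
#' @param x An \code{eln_manifest}, an \code{xml2} document, XML text, or a
#'   file path to a manifest document.
#' @return An object of class \code{eln_validation_report}: a list with a
#'   \code{violations} data frame (\code{ruleId}, \code{severity},
#'   \code{path}, \code{message}) and a logical \code{valid} that is
#'   \code{TRUE} iff no violation is an error.
#' @export
#' @examples
#' m <- eln_manifest("Record", "Oxime synthesis", "EXP-1",
#'                   eln_contact("EMail", "lab@example.org"),
#'                   eln_contributor("Author", "A. Chemist"),
#'                   "LabTrove/2.3", as.Date("2013-08-01"),
#'                   eln_content_item("Record body", "text/html"))
#' validate_manifest(m)$valid
validate_manifest <- function(x) {
  if (inherits(x, "eln_manifest")) return(validate_manifest_object(x))
  validate_manifest_doc(as_xml_doc(x))
}

# ---- object-side rules ------------------------------------------------------

soft_rules <- function(keywords_present, keywords, contributors, relatedItems) {
  v <- list()
  if (keywords_present && length(keywords[nzchar(trimws(keywords))]) == 0L)
    v[[length(v) + 1L]] <- violation("KEYWORDS_EMPTY", "warning", "Keywords",
                                     "Keywords element holds no usable terms")
  for (i in seq_along(contributors)) {
    role <- contributors[[i]]$role
    if (!tolower(trimws(role)) %in% ELN_KNOWN_ROLES)
      v[[length(v) + 1L]] <- violation(
        "ROLE_UNRECOGNIZED", "warning",
        sprintf("Contributors/Contributor[%d]/Role", i),
        sprintf("role %s is outside the customary set", dQuote(role)))
  }
  for (i in seq_along(relatedItems)) {
    r <- relatedItems[[i]]
    if (tolower(trimws(r$relationship)) == "publication" && !is_doi(r$id))
      v[[length(v) + 1L]] <- violation(
        "RELATED_ITEM_DOI_PREFERRED", "warning",
        sprintf("RelatedItems/RelatedItem[%d]/Id", i),
        sprintf("publication id %s is not a DOI; a DOI is preferred", dQuote(r$id)))
  }
  v
}

validate_manifest_object <- function(m) {
  v <- list()
  # constructor invariants guarantee the error rules; re-check defensively so
  # hand-assembled lists blessed with the class are still caught
  if (!is_nonempty_string(m$unitType) || !m$unitType %in% eln_unit_types())
    v[[length(v) + 1L]] <- violation("UNIT_TYPE_INVALID", "error", "unitType",
                                     "unitType outside {Package, Record, Component}")
  if (!is_nonempty_string(m$title))
    v[[length(v) + 1L]] <- violation("EMPTY_VALUE", "error", "Title",
                                     "title is empty")
  if (is.null(m$identifiers) ||
      !is_nonempty_string(m$identifiers$primaryLocalIdentifier)) {
    v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error",
                                     "Identifiers/PrimaryLocalIdentifier",
                                     "primary local identifier is missing")
  } else {
    if (m$identifiers$primaryLocalIdentifier %in%
        m$identifiers$otherLocalIdentifiers)
      v[[length(v) + 1L]] <- violation("IDENTIFIER_DUPLICATE", "error",
                                       "Identifiers/OtherLocalIdentifier",
                                       "duplicates the primary identifier")
    if (!is.null(m$identifiers$accessIdentifier) &&
        !is_absolute_uri(m$identifiers$accessIdentifier))
      v[[length(v) + 1L]] <- violation("ACCESS_IDENTIFIER_NOT_URI", "error",
                                       "Identifiers/AccessIdentifier",
                                       "not an absolute URI")
  }
  if (is.null(m$contact)) {
    v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error", "Contact",
                                     "contact is missing")
  } else {
    v <- c(v, contact_rules(m$contact$mode, m$contact$value, "Contact"))
  }
  if (length(m$contributors) == 0L)
    v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error",
                                     "Contributors",
                                     "at least one contributor is required")
  if (!is_nonempty_string(m$source))
    v[[length(v) + 1L]] <- violation("EMPTY_VALUE", "error", "Source",
                                     "source is empty")
  if (is.null(m$dates) || is.null(m$dates$creationDate)) {
    v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error",
                                     "Date/CreationDate",
                                     "creation date is missing")
  } else if (!is.null(m$dates$releaseDate) &&
             m$dates$releaseDate < m$dates$creationDate) {
    v[[length(v) + 1L]] <- violation("DATE_ORDER_INVALID", "error",
                                     "Date/ReleaseDate",
                                     "release date precedes creation date")
  }
  if (length(m$content) == 0L) {
    v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error", "Content",
                                     "at least one content item is required")
  } else {
    for (i in seq_along(m$content)) {
      ci <- m$content[[i]]
      if (!is_media_type(ci$dataType))
        v[[length(v) + 1L]] <- violation(
          "DATA_TYPE_SYNTAX", "error",
          sprintf("Content/ContentItem[%d]/DataType", i),
          sprintf("%s is not type/subtype syntax", dQuote(as.character(ci$dataType))))
      if (!is.null(ci$locator) && !is_absolute_uri(ci$locator))
        v[[length(v) + 1L]] <- violation(
          "LOCATOR_NOT_URI", "error",
          sprintf("Content/ContentItem[%d]/Locator", i), "not an absolute URI")
    }
  }
  v <- c(v, soft_rules(!is.null(m$keywords), m$keywords %||% character(),
                       m$contributors, m$relatedItems %||% list()))
  new_report(v)
}

contact_rules <- function(mode, value, path) {
  v <- list()
  if (!is_nonempty_string(mode) || !mode %in% eln_contact_modes()) {
    v[[length(v) + 1L]] <- violation("CONTACT_MODE_INVALID", "error", path,
                                     "contact mode outside {EMail, SystemURI, Instruction}")
    return(v)
  }
  if (!is_nonempty_string(value)) {
    v[[length(v) + 1L]] <- violation("EMPTY_VALUE", "error", path,
                                     "contact value is empty")
  } else if (mode == "EMail" && !is_email_address(value)) {
    v[[length(v) + 1L]] <- violation("CONTACT_VALUE_INVALID", "error", path,
                                     sprintf("%s is not an e-mail address", dQuote(value)))
  } else if (mode == "SystemURI" && !is_absolute_uri(value)) {
    v[[length(v) + 1L]] <- violation("CONTACT_VALUE_INVALID", "error", path,
                                     sprintf("%s is not an absolute URI", dQuote(value)))
  }
  v
}

# ---- document-side rules ----------------------------------------------------

validate_manifest_doc <- function(doc) {
  root <- xml2::xml_root(doc)
  v <- list()
  if (local_name(root) != ELN_ROOT) {
    return(new_report(list(violation(
      "MANDATORY_MISSING", "error", "/",
      sprintf("root element is <%s>, expected <%s>", local_name(root), ELN_ROOT)))))
  }
  kids <- xml2::xml_children(root)
  kid_names <- vapply(kids, local_name, character(1))
  find1 <- function(nm) {
    i <- which(kid_names == nm)
    if (length(i)) kids[[i[1]]] else NULL
  }
  ut <- xml2::xml_attr(root, "unitType")
  if (is.na(ut)) {
    v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error", "unitType",
                                     "unitType attribute is missing")
  } else if (!ut %in% eln_unit_types()) {
    v[[length(v) + 1L]] <- violation("UNIT_TYPE_INVALID", "error", "unitType",
                                     sprintf("%s outside {Package, Record, Component}", dQuote(ut)))
  }
  for (nm in c("Title", "Identifiers", "Contact", "Contributors", "Source",
               "Date", "Content")) {
    if (is.null(find1(nm)))
      v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error", nm,
                                       sprintf("mandatory element %s is absent", nm))
  }
  tn <- find1("Title")
  if (!is.null(tn) && !nzchar(trimws(xml2::xml_text(tn))))
    v[[length(v) + 1L]] <- violation("EMPTY_VALUE", "error", "Title",
                                     "title is empty")
  idn <- find1("Identifiers")
  if (!is.null(idn)) {
    prim <- xml2::xml_text(xml2::xml_children(idn)[
      vapply(xml2::xml_children(idn), local_name, character(1)) ==
        "PrimaryLocalIdentifier"])
    others <- xml2::xml_text(xml2::xml_children(idn)[
      vapply(xml2::xml_children(idn), local_name, character(1)) ==
        "OtherLocalIdentifier"])
    access <- xml2::xml_text(xml2::xml_children(idn)[
      vapply(xml2::xml_children(idn), local_name, character(1)) ==
        "AccessIdentifier"])
    if (length(prim) == 0L || !nzchar(trimws(prim[1])))
      v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error",
                                       "Identifiers/PrimaryLocalIdentifier",
                                       "primary local identifier is missing")
    else if (prim[1] %in% others)
      v[[length(v) + 1L]] <- violation("IDENTIFIER_DUPLICATE", "error",
                                       "Identifiers/OtherLocalIdentifier",
                                       "duplicates the primary identifier")
    if (length(access) && !is_absolute_uri(access[1]))
      v[[length(v) + 1L]] <- violation("ACCESS_IDENTIFIER_NOT_URI", "error",
                                       "Identifiers/AccessIdentifier",
                                       "not an absolute URI")
  }
  ctn <- find1("Contact")
  if (!is.null(ctn))
    v <- c(v, contact_rules(xml2::xml_attr(ctn, "mode"), xml2::xml_text(ctn),
                            "Contact"))
  csn <- find1("Contributors")
  contributors <- list()
  if (!is.null(csn)) {
    cons <- xml2::xml_children(csn)
    cons <- cons[vapply(cons, local_name, character(1)) == "Contributor"]
    if (length(cons) == 0L)
      v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error",
                                       "Contributors",
                                       "at least one contributor is required")
    contributors <- lapply(cons, function(cn) {
      k <- xml2::xml_children(cn)
      nm <- vapply(k, local_name, character(1))
      list(role = if (any(nm == "Role")) xml2::xml_text(k[[which(nm == "Role")[1]]]) else "",
           name = if (any(nm == "Name")) xml2::xml_text(k[[which(nm == "Name")[1]]]) else "")
    })
    for (i in seq_along(contributors))
      if (!nzchar(trimws(contributors[[i]]$name)))
        v[[length(v) + 1L]] <- violation(
          "EMPTY_VALUE", "error",
          sprintf("Contributors/Contributor[%d]/Name", i),
          "contributor name is empty")
  }
  sn <- find1("Source")
  if (!is.null(sn) && !nzchar(trimws(xml2::xml_text(sn))))
    v[[length(v) + 1L]] <- violation("EMPTY_VALUE", "error", "Source",
                                     "source is empty")
  dn <- find1("Date")
  if (!is.null(dn)) {
    k <- xml2::xml_children(dn)
    nm <- vapply(k, local_name, character(1))
    getd <- function(label) {
      i <- which(nm == label)
      if (!length(i)) return(NULL)
      txt <- xml2::xml_text(k[[i[1]]])
      d <- tryCatch(as.Date(txt, format = "%Y-%m-%d"), error = function(e) NA)
      if (is.na(d)) {
        v[[length(v) + 1L]] <<- violation(
          "DATE_SYNTAX_INVALID", "error", paste0("Date/", label),
          sprintf("%s is not an ISO 8601 date", dQuote(txt)))
        return(NULL)
      }
      d
    }
    cd <- getd("CreationDate")
    if (!any(nm == "CreationDate"))
      v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error",
                                       "Date/CreationDate",
                                       "creation date is missing")
    rd <- getd("ReleaseDate")
    if (!is.null(cd) && !is.null(rd) && rd < cd)
      v[[length(v) + 1L]] <- violation("DATE_ORDER_INVALID", "error",
                                       "Date/ReleaseDate",
                                       "release date precedes creation date")
    getd("PublicationDate")
    getd("SubmissionDate")
  }
  con <- find1("Content")
  if (!is.null(con)) {
    items <- xml2::xml_children(con)
    items <- items[vapply(items, local_name, character(1)) == "ContentItem"]
    if (length(items) == 0L)
      v[[length(v) + 1L]] <- violation("MANDATORY_MISSING", "error", "Content",
                                       "at least one content item is required")
    for (i in seq_along(items)) {
      k <- xml2::xml_children(items[[i]])
      nm <- vapply(k, local_name, character(1))
      dt <- if (any(nm == "DataType")) xml2::xml_text(k[[which(nm == "DataType")[1]]]) else ""
      if (!is_media_type(dt))
        v[[length(v) + 1L]] <- violation(
          "DATA_TYPE_SYNTAX", "error",
          sprintf("Content/ContentItem[%d]/DataType", i),
          sprintf("%s is not type/subtype syntax", dQuote(dt)))
      if (any(nm == "Locator") &&
          !is_absolute_uri(xml2::xml_text(k[[which(nm == "Locator")[1]]])))
        v[[length(v) + 1L]] <- violation(
          "LOCATOR_NOT_URI", "error",
          sprintf("Content/ContentItem[%d]/Locator", i),
          "not an absolute URI")
    }
  }
  kwn <- find1("Keywords")
  keywords <- character()
  if (!is.null(kwn)) keywords <- xml2::xml_text(xml2::xml_children(kwn))
  rin <- find1("RelatedItems")
  related <- list()
  if (!is.null(rin)) {
    related <- lapply(xml2::xml_children(rin), function(rn) {
      k <- xml2::xml_children(rn)
      nm <- vapply(k, local_name, character(1))
      list(relationship = if (any(nm == "Relationship"))
             xml2::xml_text(k[[which(nm == "Relationship")[1]]]) else "",
           id = if (any(nm == "Id")) xml2::xml_text(k[[which(nm == "Id")[1]]]) else "")
    })
  }
  v <- c(v, soft_rules(!is.null(kwn), keywords,
                       lapply(contributors, function(co)
                         list(role = co$role, name = co$name)),
                       related))
  new_report(v)
}

# ---- report methods ---------------------------------------------------------

format_report <- function(report) {
  if (nrow(report$violations) == 0L) return("valid: no violations")
  paste(sprintf("%-7s %-28s %s: %s", report$violations$severity,
                report$violations$ruleId, report$violations$path,
                report$violations$message), collapse = "\n")
}

#' @export
print.eln_validation_report <- function(x, ...) {
  cat(sprintf("<eln_validation_report> valid: %s (%d error(s), %d warning(s))\n",
              x$valid, sum(x$violations$severity == "error"),
              sum(x$violations$severity == "warning")))
  if (nrow(x$violations)) cat(format_report(x), "\n", sep = "")
  invisible(x)
}
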