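# Crosswalk from a manifest to the 15-element Dublin Core element set
# (DCMES). The mapping is fixed: title->title, keywords->subject,
# primary/access identifiers->identifier, contributors->creator (role
# Author) or contributor (all other roles), licensingBasis->rights,
# source->source, creationDate->date, relatedItems->relation, content media
# types->format, unitType->type. Values are copied verbatim; the crosswalk
# never invents or rewrites a value.

#' The 15 Dublin Core metadata elements
#'
#' @return Character vector of the DCMES element names.
#' @export
dcmes_elements <- function() {
  c("contributor", "coverage", "creator", "date", "description", "format",
    "identifier", "language", "publisher", "relation", "rights", "source",
    "subject", "title", "type")
}

dc_row <- function(element, value) {
  data.frame(element = element, value = value, stringsAsFactors = FALSE)
}

#' Crosswalk a manifest to Dublin Core
#'
#' Flattens a manifest into simple Dublin Core (element, value) pairs for
#' consumption by repository and harvesting software that only understands
#' DCMES. Every emitted element name belongs to the 15-element set and every
#' value appears verbatim in the source manifest; absent optional fields
#' emit nothing.
#'
#' @param manifest An \code{\link{eln_manifest}}.
#' @return Data frame with columns \code{element} and \code{value}, one row
#'   per emitted pair, in manifest field order.
#' @export
#' @examples
#' m <- eln_manifest("Record", "Oxime synthesis", "EXP-1",
#'                   eln_contact("EMail", "lab@example.org"),
#'                   eln_contributor("Author", "A. Chemist"),
#'                   "LabTrove/2.3", as.Date("2013-08-01"),
#'                   eln_content_item("Record body", "text/html"))
#' dc_crosswalk(m)
dc_crosswalk <- function(manifest) {
  if (!inherits(manifest, "eln_manifest"))
    stop("dc_crosswalk() expects an eln_manifest", call. = FALSE)
  rows <- list(dc_row("title", manifest$title))
  for (k in manifest$keywords %||% character())
    rows[[length(rows) + 1L]] <- dc_row("subject", k)
  rows[[length(rows) + 1L]] <-
    dc_row("identifier", manifest$identifiers$primaryLocalIdentifier)
  if (!is.null(manifest$identifiers$accessIdentifier))
    rows[[length(rows) + 1L]] <-
      dc_row("identifier", manifest$identifiers$accessIdentifier)
  for (co in manifest$contributors) {
    el <- if (tolower(trimws(co$role)) == "author") "creator" else "contributor"
    rows[[length(rows) + 1L]] <- dc_row(el, co$name)
  }
  if (!is.null(manifest$licensingBasis))
    rows[[length(rows) + 1L]] <- dc_row("rights", manifest$licensingBasis)
  rows[[length(rows) + 1L]] <- dc_row("source", manifest$source)
  rows[[length(rows) + 1L]] <- dc_row("date",
                                      format(manifest$dates$creationDate))
  for (r in manifest$relatedItems %||% list())
    rows[[length(rows) + 1L]] <- dc_row("relation", r$id)
  for (ci in manifest$content)
    rows[[length(rows) + 1L]] <- dc_row("format", ci$dataType)
  rows[[length(rows) + 1L]] <- dc_row("type", manifest$unitType)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a Dublin Core record as XML or JSON text
#'
#' @param dc Data frame from \code{\link{dc_crosswalk}}.
#' @param format Either \code{"dc-xml"} (simple \code{oai_dc}-style XML) or
#'   \code{"dc-json"}.
#' @return Single character string.
#' @export
format_dc <- function(dc, format = c("dc-xml", "dc-json")) {
  format <- match.arg(format)
  if (format == "dc-json") {
    recs <- split(dc$value, dc$element)
    return(jsonlite::toJSON(recs, auto_unbox = FALSE, pretty = TRUE))
  }
  doc <- xml2::xml_new_root("record",
                            "xmlns:dc" = "http://purl.org/dc/elements/1.1/")
  for (i in seq_len(nrow(dc)))
    xml2::xml_add_child(doc, paste0("dc:", dc$element[i]), dc$value[i])
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp), add = TRUE)
  xml2::write_xml(doc, tmp, options = "format")
  paste0(paste(readLines(tmp, encoding = "UTF-8"), collapse = "\n"), "\n")
}
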