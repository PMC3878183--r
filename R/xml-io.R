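# Versioned XML dialect for the elnItemManifest, a shipped XSD, and a
# canonical (byte-deterministic) writer/reader pair. Child order follows the
# schema's element table: Title, Keywords, Identifiers, Contact,
# LicensingBasis, Contributors, Source, Date, RelatedItems, Content; the
# unitType qualifier travels as an attribute of the root element.

ELN_NS <- "urn:eln-item-manifest:1.0"
ELN_SCHEMA_VERSION <- "1.0"
ELN_ROOT <- "elnItemManifest"

#' The XML dialect used for ELN item manifests
#'
#' @return List with the namespace URI, schema version and root element name
#'   of the manifest XML dialect.
#' @export
eln_xml_dialect <- function() {
  list(namespaceUri = ELN_NS, schemaVersion = ELN_SCHEMA_VERSION,
       rootElementName = ELN_ROOT)
}

#' Path to the shipped XML Schema Definition
#'
#' @return File path of the XSD that manifest documents validate against.
#' @export
eln_schema_path <- function() {
  p <- system.file("extdata", "elnItemManifest.xsd", package = "elnmanifest")
  if (!nzchar(p)) stop("shipped schema file not found", call. = FALSE)
  p
}

add_text_child <- function(parent, name, value) {
  xml2::xml_add_child(parent, name, as.character(value))
}

#' Serialize a manifest to canonical XML
#'
#' Produces a well-formed UTF-8 document in the versioned manifest dialect.
#' Serialization is canonical: equal manifests always yield byte-identical
#' documents, and optional fields that are absent produce no element. An
#' invalid manifest is refused together with its validation report.
#'
#' @param manifest An \code{\link{eln_manifest}}.
#' @return Single character string: the XML document, UTF-8, no BOM.
#' @seealso \code{\link{manifest_from_xml}}, \code{\link{validate_xml}}
#' @export
manifest_to_xml <- function(manifest) {
  if (!inherits(manifest, "eln_manifest"))
    stop("manifest_to_xml() expects an eln_manifest", call. = FALSE)
  report <- validate_manifest(manifest)
  if (!report$valid) {
    stop(paste0("refusing to serialize an invalid manifest:\n",
                format_report(report)), call. = FALSE)
  }
  doc <- xml2::xml_new_root(ELN_ROOT, xmlns = ELN_NS,
                            schemaVersion = ELN_SCHEMA_VERSION,
                            unitType = manifest$unitType)
  add_text_child(doc, "Title", manifest$title)
  if (!is.null(manifest$keywords)) {
    kw <- xml2::xml_add_child(doc, "Keywords")
    for (k in manifest$keywords) add_text_child(kw, "Keyword", k)
  }
  ids <- xml2::xml_add_child(doc, "Identifiers")
  add_text_child(ids, "PrimaryLocalIdentifier",
                 manifest$identifiers$primaryLocalIdentifier)
  for (o in manifest$identifiers$otherLocalIdentifiers)
    add_text_child(ids, "OtherLocalIdentifier", o)
  if (!is.null(manifest$identifiers$accessIdentifier))
    add_text_child(ids, "AccessIdentifier", manifest$identifiers$accessIdentifier)
  ct <- xml2::xml_add_child(doc, "Contact", manifest$contact$value)
  xml2::xml_set_attr(ct, "mode", manifest$contact$mode)
  if (!is.null(manifest$licensingBasis))
    add_text_child(doc, "LicensingBasis", manifest$licensingBasis)
  cs <- xml2::xml_add_child(doc, "Contributors")
  for (co in manifest$contributors) {
    cn <- xml2::xml_add_child(cs, "Contributor")
    add_text_child(cn, "Role", co$role)
    add_text_child(cn, "Name", co$name)
    for (id in co$identifiers %||% character()) add_text_child(cn, "Identifier", id)
  }
  add_text_child(doc, "Source", manifest$source)
  dt <- xml2::xml_add_child(doc, "Date")
  add_text_child(dt, "CreationDate", format(manifest$dates$creationDate))
  if (!is.null(manifest$dates$releaseDate))
    add_text_child(dt, "ReleaseDate", format(manifest$dates$releaseDate))
  if (!is.null(manifest$dates$publicationDate))
    add_text_child(dt, "PublicationDate", format(manifest$dates$publicationDate))
  if (!is.null(manifest$dates$submissionDate))
    add_text_child(dt, "SubmissionDate", format(manifest$dates$submissionDate))
  if (!is.null(manifest$relatedItems)) {
    ri <- xml2::xml_add_child(doc, "RelatedItems")
    for (r in manifest$relatedItems) {
      rn <- xml2::xml_add_child(ri, "RelatedItem")
      add_text_child(rn, "Relationship", r$relationship)
      add_text_child(rn, "Id", r$id)
    }
  }
  cont <- xml2::xml_add_child(doc, "Content")
  for (ci in manifest$content) {
    cn <- xml2::xml_add_child(cont, "ContentItem")
    add_text_child(cn, "Description", ci$description)
    add_text_child(cn, "DataType", ci$dataType)
    if (!is.null(ci$locator)) add_text_child(cn, "Locator", ci$locator)
  }
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp), add = TRUE)
  xml2::write_xml(doc, tmp, options = "format")
  paste0(paste(readLines(tmp, encoding = "UTF-8"), collapse = "\n"), "\n")
}

local_name <- function(node) xml2::xml_name(node, ns = character())

# dialect-namespace children of a node, erroring on unknown dialect elements
# and ignoring (with one warning) elements from foreign namespaces
dialect_children <- function(node, allowed, path) {
  kids <- xml2::xml_children(node)
  keep <- list()
  for (k in kids) {
    uri <- xml_node_ns_uri(k)
    nm <- local_name(k)
    if (!identical(uri, ELN_NS)) {
      warning(sprintf("ignoring foreign-namespace element <%s> under %s",
                      nm, path), call. = FALSE)
      next
    }
    if (!nm %in% allowed)
      stop(sprintf("unknown element <%s> in manifest namespace under %s",
                   nm, path), call. = FALSE)
    keep[[length(keep) + 1L]] <- k
  }
  keep
}

xml_node_ns_uri <- function(node) {
  xml2::xml_find_chr(node, "string(namespace-uri(.))")
}

child_texts <- function(kids, name) {
  vals <- vapply(Filter(function(k) local_name(k) == name, kids),
                 xml2::xml_text, character(1))
  as.character(vals)
}

#' Parse a manifest from XML
#'
#' Reads a document in the manifest dialect back into an
#' \code{\link{eln_manifest}}. For any valid manifest \code{m},
#' \code{manifest_from_xml(manifest_to_xml(m))} is identical to \code{m}.
#' Unknown elements in the manifest namespace are an error; elements from
#' foreign namespaces are ignored with a warning, so extended documents
#' still read.
#'
#' @param x XML text, a file path, or an \code{xml2} document.
#' @return An \code{\link{eln_manifest}}.
#' @export
manifest_from_xml <- function(x) {
  doc <- as_xml_doc(x)
  root <- xml2::xml_root(doc)
  if (local_name(root) != ELN_ROOT)
    stop(sprintf("root element must be <%s>, found <%s>",
                 ELN_ROOT, local_name(root)), call. = FALSE)
  report <- validate_manifest(doc)
  errs <- report$violations[report$violations$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop(paste0("document is not a valid manifest:\n", format_report(report)),
         call. = FALSE)
  top <- dialect_children(root, c("Title", "Keywords", "Identifiers", "Contact",
                                  "LicensingBasis", "Contributors", "Source",
                                  "Date", "RelatedItems", "Content"),
                          ELN_ROOT)
  get1 <- function(name) Filter(function(k) local_name(k) == name, top)
  text1 <- function(name) {
    n <- get1(name)
    if (length(n)) xml2::xml_text(n[[1]]) else NULL
  }
  keywords <- NULL
  kwn <- get1("Keywords")
  if (length(kwn))
    keywords <- child_texts(dialect_children(kwn[[1]], "Keyword", "Keywords"),
                            "Keyword")
  idn <- dialect_children(get1("Identifiers")[[1]],
                          c("PrimaryLocalIdentifier", "OtherLocalIdentifier",
                            "AccessIdentifier"), "Identifiers")
  access <- child_texts(idn, "AccessIdentifier")
  identifiers <- eln_identifier_set(
    child_texts(idn, "PrimaryLocalIdentifier")[1],
    child_texts(idn, "OtherLocalIdentifier"),
    if (length(access)) access[1] else NULL)
  ctn <- get1("Contact")[[1]]
  contact <- eln_contact(xml2::xml_attr(ctn, "mode"), xml2::xml_text(ctn))
  contributors <- lapply(
    dialect_children(get1("Contributors")[[1]], "Contributor", "Contributors"),
    function(cn) {
      kids <- dialect_children(cn, c("Role", "Name", "Identifier"),
                               "Contributors/Contributor")
      ids <- child_texts(kids, "Identifier")
      eln_contributor(child_texts(kids, "Role")[1],
                      child_texts(kids, "Name")[1],
                      if (length(ids)) ids else NULL)
    })
  dtn <- dialect_children(get1("Date")[[1]],
                          c("CreationDate", "ReleaseDate", "PublicationDate",
                            "SubmissionDate"), "Date")
  opt_date <- function(name) {
    v <- child_texts(dtn, name)
    if (length(v)) as.Date(v[1]) else NULL
  }
  dates <- eln_date_set(as.Date(child_texts(dtn, "CreationDate")[1]),
                        opt_date("ReleaseDate"), opt_date("PublicationDate"),
                        opt_date("SubmissionDate"))
  relatedItems <- NULL
  rin <- get1("RelatedItems")
  if (length(rin)) {
    items <- lapply(
      dialect_children(rin[[1]], "RelatedItem", "RelatedItems"),
      function(rn) {
        kids <- dialect_children(rn, c("Relationship", "Id"),
                                 "RelatedItems/RelatedItem")
        eln_related_item(child_texts(kids, "Relationship")[1],
                         child_texts(kids, "Id")[1])
      })
    if (length(items)) relatedItems <- items
  }
  content <- lapply(
    dialect_children(get1("Content")[[1]], "ContentItem", "Content"),
    function(cn) {
      kids <- dialect_children(cn, c("Description", "DataType", "Locator"),
                               "Content/ContentItem")
      loc <- child_texts(kids, "Locator")
      eln_content_item(child_texts(kids, "Description")[1],
                       child_texts(kids, "DataType")[1],
                       if (length(loc)) loc[1] else NULL)
    })
  eln_manifest(unitType = xml2::xml_attr(root, "unitType"),
               title = text1("Title"), identifiers = identifiers,
               contact = contact, contributors = contributors,
               source = text1("Source"), dates = dates, content = content,
               keywords = keywords, licensingBasis = text1("LicensingBasis"),
               relatedItems = relatedItems)
}

as_xml_doc <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE) &&
      file.exists(x))
    return(xml2::read_xml(x))
  xml2::read_xml(paste(x, collapse = "\n"))
}

#' Validate a manifest document against the shipped XSD
#'
#' @param x XML text, a file path, or an \code{xml2} document.
#' @return Logical scalar; attribute \code{"errors"} carries the validator
#'   messages when \code{FALSE}.
#' @export
validate_xml <- function(x) {
  doc <- as_xml_doc(x)
  schema <- xml2::read_xml(eln_schema_path())
  xml2::xml_validate(doc, schema)
}

#' Write a manifest to an XML file
#'
#' @param manifest An \code{\link{eln_manifest}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(manifest_to_xml(manifest), path, useBytes = TRUE)
  invisible(path)
}

#' Read a manifest from an XML file
#'
#' @param path Path of a manifest XML document.
#' @return An \code{\link{eln_manifest}}.
#' @export
read_manifest <- function(path) manifest_from_xml(xml2::read_xml(path))
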