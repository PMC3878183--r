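# Deriving manifests from source ELN records. The source is a neutral
# description of what a blog-style ELN (permalinked HTML posts with
# attachments) or an experiment-database ELN (experiment ids, structured
# attachments) exposes; site-wide contact/contributor details come from a
# plugin configuration file, and the licensing basis and embargo period are
# entered per deposition by the user.

#' A neutral source ELN record
#'
#' @param localId Experiment id or permalink URL locating the record in the
#'   originating ELN; becomes the manifest's primary local identifier.
#' @param title Record title.
#' @param authors List of \code{c(role, name)} pairs (or a 2-column matrix /
#'   list of 2-vectors) naming the record's authors as the ELN exposes them.
#' @param createdOn Calendar date the record was created.
#' @param systemName,systemVersion Generating software and its version.
#' @param attachments List of attachment descriptors, each a list with
#'   \code{filename}, \code{mediaType}, \code{description} and optional
#'   \code{locator}. A missing media type is substituted with
#'   \code{"application/octet-stream"} and a warning.
#' @param relatedPublications List of \code{c(relationship, id)} pairs.
#' @param bodyMediaType Media type of the record body, e.g. \code{text/html}.
#' @return An object of class \code{eln_record_source}.
#' @export
eln_record_source <- function(localId, title, authors, createdOn,
                              systemName, systemVersion,
                              attachments = list(),
                              relatedPublications = list(),
                              bodyMediaType = "text/html") {
  if (!is_nonempty_string(localId))
    stop("source record localId must be non-empty", call. = FALSE)
  if (!is_nonempty_string(title))
    stop("source record title must be non-empty", call. = FALSE)
  structure(list(localId = localId, title = title,
                 authors = lapply(authors, function(a)
                   list(role = as.character(a[[1]]), name = as.character(a[[2]]))),
                 createdOn = as_eln_date(createdOn, "createdOn"),
                 systemName = systemName, systemVersion = systemVersion,
                 attachments = attachments,
                 relatedPublications = lapply(relatedPublications, function(p)
                   list(relationship = as.character(p[[1]]),
                        id = as.character(p[[2]]))),
                 bodyMediaType = bodyMediaType),
            class = "eln_record_source")
}

#' Site configuration for manifest generation
#'
#' The contact and contributor details that are constant across depositions
#' from one installation, as saved in the deposition plugin's configuration
#' file.
#'
#' @param contact An \code{\link{eln_contact}}.
#' @param contributors Non-empty list of \code{\link{eln_contributor}}s.
#' @return An object of class \code{eln_site_config}.
#' @export
eln_site_config <- function(contact, contributors) {
  if (!inherits(contact, "eln_contact"))
    stop("site config contact must be an eln_contact", call. = FALSE)
  contributors <- as_item_list(contributors, "eln_contributor", "Contributors")
  if (length(contributors) == 0L)
    stop("site config must name at least one contributor", call. = FALSE)
  structure(list(contact = contact, contributors = contributors),
            class = "eln_site_config")
}

#' Per-deposition user input
#'
#' Licensing basis and embargo period are entered by the user at deposition
#' time, since they may change from one deposition to the next; the
#' manifest's release date is calculated from the embargo.
#'
#' @param licensingBasis Optional license name, e.g. \code{"CC-BY-4.0"}.
#' @param embargo Optional non-negative ISO 8601 duration, e.g. \code{"P6M"}.
#' @return An object of class \code{eln_user_input}.
#' @export
eln_user_input <- function(licensingBasis = NULL, embargo = NULL) {
  if (!is.null(embargo)) parse_iso_duration(embargo)  # rejects negatives
  structure(list(licensingBasis = licensingBasis, embargo = embargo),
            class = "eln_user_input")
}

#' Derive a manifest from a source ELN record
#'
#' Assembles an \code{\link{eln_manifest}} from the three places the fields
#' live: the ELN record itself (identifier, title, authors, dates,
#' attachments, related publications), the site configuration (contact,
#' standing contributors) and the user's per-deposition input (licensing
#' basis, embargo). The source field is
#' \code{systemName/systemVersion}, resembling a browser user agent. The
#' record body is always listed as a content item, so the mandatory content
#' list is non-empty even for attachment-free records; each attachment adds
#' one further item. Contributors from the config and the record's authors
#' are merged and deduplicated on (role, name). When an embargo is given,
#' \code{releaseDate = compute_release_date(createdOn, embargo)}.
#'
#' @param source An \code{\link{eln_record_source}}.
#' @param config An \code{\link{eln_site_config}}.
#' @param user An \code{\link{eln_user_input}}.
#' @param unitType Unit type of the derived manifest; default \code{"Record"}.
#' @return A valid \code{\link{eln_manifest}}.
#' @export
derive_manifest <- function(source, config, user = eln_user_input(),
                            unitType = "Record") {
  if (!inherits(source, "eln_record_source"))
    stop("derive_manifest() expects an eln_record_source", call. = FALSE)
  if (!inherits(config, "eln_site_config"))
    stop("derive_manifest() expects an eln_site_config", call. = FALSE)
  contributors <- config$contributors
  seen <- vapply(contributors, function(co) paste0(co$role, "\r", co$name),
                 character(1))
  for (a in source$authors) {
    key <- paste0(a$role, "\r", a$name)
    if (!key %in% seen) {
      contributors[[length(contributors) + 1L]] <- eln_contributor(a$role, a$name)
      seen <- c(seen, key)
    }
  }
  content <- list(eln_content_item("Record body", source$bodyMediaType))
  for (at in source$attachments) {
    mt <- at$mediaType
    if (is.null(mt) || !is_media_type(mt)) {
      warning(sprintf("attachment %s has no usable media type; using application/octet-stream",
                      dQuote(at$filename %||% "?")), call. = FALSE)
      mt <- "application/octet-stream"
    }
    content[[length(content) + 1L]] <-
      eln_content_item(at$description %||% at$filename, mt, at$locator)
  }
  relatedItems <- NULL
  if (length(source$relatedPublications))
    relatedItems <- lapply(source$relatedPublications, function(p)
      eln_related_item(p$relationship, p$id))
  dates <- if (!is.null(user$embargo)) {
    eln_date_set(source$createdOn,
                 releaseDate = compute_release_date(source$createdOn,
                                                    user$embargo))
  } else {
    eln_date_set(source$createdOn)
  }
  eln_manifest(unitType = unitType, title = source$title,
               identifiers = eln_identifier_set(source$localId),
               contact = config$contact, contributors = contributors,
               source = paste0(source$systemName, "/", source$systemVersion),
               dates = dates, content = content,
               licensingBasis = user$licensingBasis,
               relatedItems = relatedItems)
}

# ---- site configuration file (flat key = value text format) -----------------
#
#   contact.mode = EMail
#   contact.value = curator@example.org
#   contributor.1.role = Author
#   contributor.1.name = A. Chemist
#   contributor.1.identifiers = https://orcid.org/0000-0000-0000-0000
#
# identifiers are ";"-separated; blank lines and "#" comments are ignored.

#' Read a site configuration file
#'
#' @param path Path to a flat \code{key = value} configuration file (see
#'   \code{\link{save_site_config}} for the format).
#' @return An \code{\link{eln_site_config}}.
#' @export
load_site_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("site config file %s does not exist", dQuote(path)),
         call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad))
    stop(sprintf("cannot parse site config line %s", dQuote(bad[1])),
         call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- vapply(kv, `[[`, character(1), 3)
  getv <- function(key) {
    i <- which(keys == key)
    if (!length(i)) stop(sprintf("site config is missing key %s", dQuote(key)),
                         call. = FALSE)
    vals[i[1]]
  }
  contact <- eln_contact(getv("contact.mode"), getv("contact.value"))
  idx <- sort(unique(as.integer(sub("^contributor\\.([0-9]+)\\..*$", "\\1",
                                    keys[grepl("^contributor\\.[0-9]+\\.", keys)]))))
  if (!length(idx))
    stop("site config names no contributors (contributor.N.role/name keys)",
         call. = FALSE)
  contributors <- lapply(idx, function(i) {
    ids <- NULL
    key <- sprintf("contributor.%d.identifiers", i)
    if (key %in% keys) {
      ids <- strsplit(getv(key), ";", fixed = TRUE)[[1]]
      ids <- trimws(ids)[nzchar(trimws(ids))]
      if (!length(ids)) ids <- NULL
    }
    eln_contributor(getv(sprintf("contributor.%d.role", i)),
                    getv(sprintf("contributor.%d.name", i)), ids)
  })
  eln_site_config(contact, contributors)
}

#' Write a site configuration file
#'
#' @param config An \code{\link{eln_site_config}}.
#' @param path Output path.
#' @return \code{path}, invisibly. \code{load_site_config(path)} returns an
#'   identical configuration.
#' @export
save_site_config <- function(config, path) {
  if (!inherits(config, "eln_site_config"))
    stop("save_site_config() expects an eln_site_config", call. = FALSE)
  lines <- c(sprintf("contact.mode = %s", config$contact$mode),
             sprintf("contact.value = %s", config$contact$value))
  for (i in seq_along(config$contributors)) {
    co <- config$contributors[[i]]
    lines <- c(lines,
               sprintf("contributor.%d.role = %s", i, co$role),
               sprintf("contributor.%d.name = %s", i, co$name))
    if (!is.null(co$identifiers))
      lines <- c(lines, sprintf("contributor.%d.identifiers = %s", i,
                                paste(co$identifiers, collapse = ";")))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- JSON serialization of source records (for the CLI) ---------------------

#' Write a source record as JSON
#'
#' @param source An \code{\link{eln_record_source}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_record_json <- function(source, path) {
  x <- unclass(source)
  x$createdOn <- format(x$createdOn)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a source record from JSON
#'
#' @param path Path written by \code{\link{write_record_json}}.
#' @return An \code{\link{eln_record_source}}.
#' @export
read_record_json <- function(path) {
  x <- jsonlite::read_json(path)
  eln_record_source(
    localId = x$localId, title = x$title,
    authors = lapply(x$authors, function(a) c(a$role, a$name)),
    createdOn = as.Date(x$createdOn),
    systemName = x$systemName, systemVersion = x$systemVersion,
    attachments = lapply(x$attachments %||% list(), function(at)
      list(filename = at$filename, mediaType = at$mediaType,
           description = at$description, locator = at$locator)),
    relatedPublications = lapply(x$relatedPublications %||% list(),
                                 function(p) c(p$relationship, p$id)),
    bodyMediaType = x$bodyMediaType %||% "text/html")
}
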