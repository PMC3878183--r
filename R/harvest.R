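# A harvestable knowledge-layer feed over a collection of manifests, in the
# style of OAI-PMH list requests: filterable, paginated with opaque
# resumption tokens, and backed either by memory or by a directory of
# manifest XML files. Three-tier resolution projects a manifest onto the
# knowledge / information / processing layers of the metadata model.

#' Tier names of the layered metadata model
#'
#' @return Character vector: \code{"knowledge"}, \code{"information"},
#'   \code{"processing"}.
#' @export
eln_tiers <- function() c("knowledge", "information", "processing")

#' Create a manifest store
#'
#' @param entries Optional list of entries as produced by
#'   \code{\link{store_add}}.
#' @return An object of class \code{eln_manifest_store}.
#' @export
manifest_store <- function(entries = list()) {
  ids <- vapply(entries, `[[`, character(1), "storeId")
  if (anyDuplicated(ids))
    stop("store ids must be unique", call. = FALSE)
  structure(list(entries = entries), class = "eln_manifest_store")
}

#' Add a manifest to a store
#'
#' @param store An \code{eln_manifest_store}.
#' @param manifest An \code{\link{eln_manifest}}.
#' @param storeId Unique identifier of the entry within the store.
#' @param lastModified Modification timestamp (\code{POSIXct}).
#' @return The enlarged store.
#' @export
store_add <- function(store, manifest, storeId, lastModified) {
  if (!inherits(manifest, "eln_manifest"))
    stop("store_add() expects an eln_manifest", call. = FALSE)
  ids <- vapply(store$entries, `[[`, character(1), "storeId")
  if (storeId %in% ids)
    stop(sprintf("store id %s already present", dQuote(storeId)), call. = FALSE)
  store$entries[[length(store$entries) + 1L]] <-
    list(storeId = storeId, manifest = manifest,
         lastModified = as.POSIXct(lastModified, tz = "UTC"))
  store
}

#' @export
print.eln_manifest_store <- function(x, ...) {
  cat(sprintf("<eln_manifest_store> %d manifest(s)\n", length(x$entries)))
  invisible(x)
}

#' Write a store to a directory of manifest XML files
#'
#' One file per entry, named \code{<storeId>.xml}; file modification times
#' carry the entries' lastModified stamps.
#'
#' @param store An \code{eln_manifest_store}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in store$entries) {
    path <- file.path(dir, paste0(e$storeId, ".xml"))
    write_manifest(e$manifest, path)
    Sys.setFileTime(path, e$lastModified)
  }
  invisible(dir)
}

#' Read a store from a directory of manifest XML files
#'
#' @param dir Directory holding \code{*.xml} manifest documents; file names
#'   (minus extension) become store ids and file modification times the
#'   lastModified stamps.
#' @return An \code{eln_manifest_store}.
#' @export
read_store <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  entries <- lapply(files, function(f) {
    list(storeId = sub("\\.xml$", "", basename(f)),
         manifest = read_manifest(f),
         lastModified = as.POSIXct(file.mtime(f), tz = "UTC"))
  })
  manifest_store(entries)
}

#' A harvesting filter
#'
#' Every constraint is optional; an empty filter matches every manifest.
#'
#' @param unitTypes Optional character vector of acceptable unit types.
#' @param mediaTypes Optional character vector; matches when some content
#'   item has one of these data types (exact, case-sensitive).
#' @param keywordsAny Optional character vector; matches when the manifest's
#'   keyword set intersects it (case-sensitive).
#' @param requireReleased If \code{TRUE}, matches only manifests whose
#'   release date is absent or not after \code{today} (embargo has lifted).
#' @param licensePrefix Optional prefix the licensing basis must start with
#'   (case-insensitive); manifests without a licensing basis do not match.
#' @param modifiedSince Optional timestamp; entries modified before it are
#'   excluded at the feed level.
#' @return An object of class \code{eln_filter_spec}.
#' @export
filter_spec <- function(unitTypes = NULL, mediaTypes = NULL,
                        keywordsAny = NULL, requireReleased = FALSE,
                        licensePrefix = NULL, modifiedSince = NULL) {
  structure(list(unitTypes = unitTypes, mediaTypes = mediaTypes,
                 keywordsAny = keywordsAny,
                 requireReleased = isTRUE(requireReleased),
                 licensePrefix = licensePrefix,
                 modifiedSince = if (is.null(modifiedSince)) NULL
                                 else as.POSIXct(modifiedSince, tz = "UTC")),
            class = "eln_filter_spec")
}

#' Does a manifest match a filter?
#'
#' Evaluates every present constraint; all must hold. Matching is
#' case-sensitive except for the license prefix. The \code{modifiedSince}
#' constraint concerns store timestamps, not the manifest, and is applied by
#' \code{\link{list_manifests}}.
#'
#' @param manifest An \code{\link{eln_manifest}}.
#' @param filter An \code{\link{filter_spec}}.
#' @param today Reference date for the embargo check.
#' @return Logical scalar.
#' @export
manifest_matches <- function(manifest, filter, today = Sys.Date()) {
  if (!is.null(filter$unitTypes) && !manifest$unitType %in% filter$unitTypes)
    return(FALSE)
  if (!is.null(filter$mediaTypes)) {
    dts <- vapply(manifest$content, `[[`, character(1), "dataType")
    if (!any(dts %in% filter$mediaTypes)) return(FALSE)
  }
  if (!is.null(filter$keywordsAny)) {
    if (length(intersect(manifest$keywords %||% character(),
                         filter$keywordsAny)) == 0L)
      return(FALSE)
  }
  if (filter$requireReleased) {
    rd <- manifest$dates$releaseDate
    if (!is.null(rd) && rd > today) return(FALSE)
  }
  if (!is.null(filter$licensePrefix)) {
    lb <- manifest$licensingBasis
    if (is.null(lb) ||
        !startsWith(tolower(lb), tolower(filter$licensePrefix)))
      return(FALSE)
  }
  TRUE
}

# 32-bit FNV-1a over a canonical serialization; used only to tie resumption
# tokens to the filter and page size they were issued for
fnv1a <- function(text) {
  mul32 <- function(a, b) {
    lo <- a %% 65536
    hi <- (a %/% 65536) %% 65536
    (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
  }
  bytes <- utf8ToInt(enc2utf8(text))
  h <- 2166136261
  for (b in bytes) {
    # xor on doubles below 2^32, via 16-bit halves
    hl <- h %% 65536; hh <- h %/% 65536
    bl <- b %% 65536; bh <- b %/% 65536
    h <- bitwXor(as.integer(hl), as.integer(bl)) +
      bitwXor(as.integer(hh), as.integer(bh)) * 65536
    h <- mul32(h, 16777619)
  }
  h
}

filter_fingerprint <- function(filter, pageSize) {
  key <- paste(
    paste(filter$unitTypes %||% "", collapse = ","),
    paste(filter$mediaTypes %||% "", collapse = ","),
    paste(filter$keywordsAny %||% "", collapse = ","),
    filter$requireReleased,
    filter$licensePrefix %||% "",
    if (is.null(filter$modifiedSince)) "" else
      format(filter$modifiedSince, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    pageSize, sep = "|")
  h <- fnv1a(key)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

make_token <- function(fingerprint, offset) {
  sprintf("eln1-%s-%d", fingerprint, offset)
}

parse_token <- function(token, fingerprint) {
  m <- regmatches(token, regexec("^eln1-([0-9a-f]{8})-([0-9]+)$", token))[[1]]
  if (length(m) != 3L)
    stop(sprintf("malformed resumption token %s", dQuote(token)), call. = FALSE)
  if (m[2] != fingerprint)
    stop("resumption token does not belong to this filter/page size",
         call. = FALSE)
  as.integer(m[3])
}

#' List manifests from a store, paginated
#'
#' Applies the filter to every entry, orders matches by (lastModified,
#' storeId) and returns one page of summaries plus, when more matches
#' remain, an opaque resumption token for the next page. Concatenating all
#' pages yields each matched manifest exactly once.
#'
#' @param store An \code{eln_manifest_store}.
#' @param filter An \code{\link{filter_spec}}.
#' @param pageSize Positive page size.
#' @param resumptionToken Token returned by the previous call, or
#'   \code{NULL} for the first page. A token issued for a different filter
#'   or page size is rejected.
#' @param today Reference date for the embargo constraint.
#' @return List with \code{summaries} (data frame: \code{storeId},
#'   \code{title}, \code{unitType}, \code{primaryLocalIdentifier},
#'   \code{lastModified}), \code{storeIds}, and \code{resumptionToken}
#'   (\code{NULL} on the final page).
#' @export
list_manifests <- function(store, filter = filter_spec(), pageSize = 10L,
                           resumptionToken = NULL, today = Sys.Date()) {
  if (!is.numeric(pageSize) || pageSize < 1)
    stop("pageSize must be a positive integer", call. = FALSE)
  pageSize <- as.integer(pageSize)
  fp <- filter_fingerprint(filter, pageSize)
  offset <- if (is.null(resumptionToken)) 0L else parse_token(resumptionToken, fp)
  entries <- store$entries
  if (!is.null(filter$modifiedSince))
    entries <- Filter(function(e) e$lastModified >= filter$modifiedSince,
                      entries)
  entries <- Filter(function(e) manifest_matches(e$manifest, filter, today),
                    entries)
  if (length(entries)) {
    ord <- order(vapply(entries, function(e)
                   format(e$lastModified, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   character(1)),
                 vapply(entries, `[[`, character(1), "storeId"))
    entries <- entries[ord]
  }
  n <- length(entries)
  if (offset > n)
    stop("resumption token is past the end of the matched set", call. = FALSE)
  take <- entries[seq_len(n) > offset & seq_len(n) <= offset + pageSize]
  summaries <- data.frame(
    storeId = vapply(take, `[[`, character(1), "storeId"),
    title = vapply(take, function(e) e$manifest$title, character(1)),
    unitType = vapply(take, function(e) e$manifest$unitType, character(1)),
    primaryLocalIdentifier = vapply(take, function(e)
      e$manifest$identifiers$primaryLocalIdentifier, character(1)),
    lastModified = vapply(take, function(e)
      format(e$lastModified, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), character(1)),
    stringsAsFactors = FALSE)
  nxt <- if (offset + pageSize < n) make_token(fp, offset + pageSize) else NULL
  list(summaries = summaries,
       storeIds = summaries$storeId,
       resumptionToken = nxt)
}

#' Harvest the complete matched set, page by page
#'
#' Convenience driver around \code{\link{list_manifests}} that follows
#' resumption tokens to exhaustion.
#'
#' @inheritParams list_manifests
#' @return Character vector of matched store ids, in feed order.
#' @export
harvest_all <- function(store, filter = filter_spec(), pageSize = 10L,
                        today = Sys.Date()) {
  ids <- character()
  token <- NULL
  repeat {
    page <- list_manifests(store, filter, pageSize, token, today)
    ids <- c(ids, page$storeIds)
    if (is.null(page$resumptionToken)) break
    token <- page$resumptionToken
  }
  ids
}

#' Project a manifest onto one tier of the layered metadata model
#'
#' The manifest itself plays the role of the knowledge layer; its related
#' items are the route into the information layer; its content list (plus
#' the access identifier, when present) is the access point to the
#' processing layer.
#'
#' @param manifest An \code{\link{eln_manifest}}.
#' @param tier One of \code{eln_tiers()}.
#' @return For \code{"knowledge"}: an \code{eln_manifest} holding the
#'   descriptive core (related items removed, content locators stripped).
#'   For \code{"information"}: the list of related items (possibly empty).
#'   For \code{"processing"}: a list with \code{content} (the content items)
#'   and \code{accessIdentifier} (or \code{NULL}).
#' @export
resolve_tier <- function(manifest, tier) {
  if (!is.character(tier) || length(tier) != 1L || !tier %in% eln_tiers())
    stop(sprintf("unknown tier %s; valid tiers are: %s",
                 dQuote(as.character(tier)[1]),
                 paste(eln_tiers(), collapse = ", ")), call. = FALSE)
  if (!inherits(manifest, "eln_manifest"))
    stop("resolve_tier() expects an eln_manifest", call. = FALSE)
  switch(tier,
    knowledge = {
      m <- manifest
      m$relatedItems <- NULL
      m$content <- lapply(m$content, function(ci)
        eln_content_item(ci$description, ci$dataType))
      m
    },
    information = manifest$relatedItems %||% list(),
    processing = list(content = manifest$content,
                      accessIdentifier = manifest$identifiers$accessIdentifier))
}
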