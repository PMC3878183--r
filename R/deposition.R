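# Repository deposition packaging: one SDF file per deposition carrying the
# chemical structures (molfile V2000 blocks) with basic provenance in the
# per-record data fields (author, principal investigator, ELN experiment
# id), accompanied by the full manifest as a separate XML file. The inverse
# splitter recovers structures and metadata for verification. Molfiles are
# treated as opaque validated text (counts-line check only); no chemical
# perception is done.

SDF_FIELD_AUTHOR <- "AUTHOR"
SDF_FIELD_PI <- "PRINCIPAL_INVESTIGATOR"
SDF_FIELD_EXPERIMENT <- "ELN_EXPERIMENT_ID"

# a molfile is accepted if line 4 is a V2000 counts line
check_counts_line <- function(mol, index) {
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 5L)
    stop(sprintf("structure %d: molfile too short to hold a counts line", index),
         call. = FALSE)
  counts <- lines[4]
  if (!grepl("^\\s*[0-9]+\\s+[0-9]+(\\s|[0-9]).*V2000\\s*$", counts))
    stop(sprintf("structure %d: line 4 (%s) is not a V2000 counts line",
                 index, dQuote(counts)), call. = FALSE)
  invisible(TRUE)
}

manifest_role_value <- function(manifest, roles, fallback_first) {
  for (co in manifest$contributors)
    if (tolower(trimws(co$role)) %in% roles) return(co$name)
  if (fallback_first) manifest$contributors[[1]]$name else ""
}

#' Package structures and a manifest for deposition
#'
#' Builds a single SDF containing every structure, each molfile block
#' followed by the three provenance data fields \code{AUTHOR} (the first
#' contributor with role Author, else the first contributor),
#' \code{PRINCIPAL_INVESTIGATOR} (the first contributor with role PI or
#' Principal Investigator, else empty) and \code{ELN_EXPERIMENT_ID}, and
#' terminated by \code{$$$$}. The fields are replicated into every record so
#' the file survives record-wise splitting. The manifest travels alongside
#' as a separate serialized elnItemManifest document.
#'
#' @param structures Non-empty list (or character vector) of molfile texts;
#'   each must carry a parseable V2000 counts line.
#' @param manifest A valid \code{\link{eln_manifest}}.
#' @param experimentId The originating ELN experiment identifier.
#' @return An object of class \code{eln_deposition_package}: list with
#'   \code{sdf} (the SDF text) and \code{manifestFile} (the manifest XML
#'   text).
#' @export
package_deposition <- function(structures, manifest, experimentId) {
  structures <- as.list(structures)
  if (length(structures) == 0L)
    stop("at least one structure is required for a deposition", call. = FALSE)
  if (!is_nonempty_string(experimentId))
    stop("experimentId must be a non-empty string", call. = FALSE)
  manifest_xml <- manifest_to_xml(manifest)  # also rejects invalid manifests
  author <- manifest_role_value(manifest, "author", fallback_first = TRUE)
  pi <- manifest_role_value(manifest, c("pi", "principal investigator"),
                            fallback_first = FALSE)
  records <- vapply(seq_along(structures), function(i) {
    mol <- structures[[i]]
    check_counts_line(mol, i)
    mol <- sub("\n+$", "", mol)  # one canonical newline before data fields
    paste0(mol, "\n",
           "> <", SDF_FIELD_AUTHOR, ">\n", author, "\n\n",
           "> <", SDF_FIELD_PI, ">\n", pi, "\n\n",
           "> <", SDF_FIELD_EXPERIMENT, ">\n", experimentId, "\n\n",
           "$$$$\n")
  }, character(1))
  structure(list(sdf = paste(records, collapse = ""),
                 manifestFile = manifest_xml),
            class = "eln_deposition_package")
}

#' @export
print.eln_deposition_package <- function(x, ...) {
  n <- length(gregexpr("\\$\\$\\$\\$", x$sdf)[[1]])
  cat(sprintf("<eln_deposition_package> %d structure record(s), manifest %d bytes\n",
              n, nchar(x$manifestFile, type = "bytes")))
  invisible(x)
}

parse_sdf_record <- function(lines, index) {
  field_start <- grep("^>\\s*<", lines)
  if (length(field_start) == 0L)
    stop(sprintf("record %d carries no data fields", index), call. = FALSE)
  mol_lines <- lines[seq_len(field_start[1] - 1L)]
  fields <- list()
  i <- field_start[1]
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^>\\s*<([^>]+)>", lines[i]))[[1]]
    if (length(m) == 2L) {
      vals <- character()
      j <- i + 1L
      while (j <= length(lines) && nzchar(lines[j])) {
        vals <- c(vals, lines[j])
        j <- j + 1L
      }
      fields[[m[2]]] <- paste(vals, collapse = "\n")
      i <- j
    } else {
      i <- i + 1L
    }
  }
  list(mol = paste0(paste(mol_lines, collapse = "\n"), "\n"), fields = fields)
}

#' Split a deposition package back into structures and metadata
#'
#' Inverse of \code{\link{package_deposition}}: recovers the molfile texts
#' (data fields stripped), the (author, principal investigator, experiment
#' id) provenance triple, and the manifest. The provenance fields must agree
#' across all records of the SDF; disagreement is an error.
#'
#' @param package An \code{eln_deposition_package}, or a list with
#'   \code{sdf} and \code{manifestFile} texts.
#' @return List with \code{structures} (character vector of molfile texts),
#'   \code{metadata} (list \code{author}, \code{principalInvestigator},
#'   \code{experimentId}) and \code{manifest} (an
#'   \code{\link{eln_manifest}}).
#' @export
split_deposition <- function(package) {
  if (!is.list(package) || is.null(package$sdf) || is.null(package$manifestFile))
    stop("split_deposition() expects a deposition package with sdf and manifestFile",
         call. = FALSE)
  lines <- strsplit(package$sdf, "\n", fixed = TRUE)[[1]]
  term <- which(trimws(lines) == "$$$$")
  if (length(term) == 0L)
    stop("malformed SDF: no $$$$ record terminator found", call. = FALSE)
  starts <- c(1L, term[-length(term)] + 1L)
  if (term[length(term)] < length(lines) &&
      any(nzchar(lines[(term[length(term)] + 1L):length(lines)])))
    stop("malformed SDF: content after the final $$$$ terminator", call. = FALSE)
  recs <- lapply(seq_along(term), function(i) {
    rl <- lines[starts[i]:(term[i] - 1L)]
    parse_sdf_record(rl, i)
  })
  triples <- lapply(recs, function(r) {
    list(author = r$fields[[SDF_FIELD_AUTHOR]] %||% NA_character_,
         principalInvestigator = r$fields[[SDF_FIELD_PI]] %||% NA_character_,
         experimentId = r$fields[[SDF_FIELD_EXPERIMENT]] %||% NA_character_)
  })
  first <- triples[[1]]
  for (i in seq_along(triples)) {
    if (!identical(triples[[i]], first))
      stop(sprintf("record %d provenance fields disagree with record 1", i),
           call. = FALSE)
  }
  list(structures = vapply(recs, `[[`, character(1), "mol"),
       metadata = first,
       manifest = manifest_from_xml(package$manifestFile))
}

#' Write a deposition package to disk
#'
#' @param package An \code{eln_deposition_package}.
#' @param sdfPath Output path for the SDF.
#' @param manifestPath Output path for the separate manifest XML file.
#' @return Invisibly, \code{c(sdfPath, manifestPath)}.
#' @export
write_deposition <- function(package, sdfPath, manifestPath) {
  cat(package$sdf, file = sdfPath)
  cat(package$manifestFile, file = manifestPath)
  invisible(c(sdfPath, manifestPath))
}
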