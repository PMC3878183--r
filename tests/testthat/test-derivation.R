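source_fixture <- function(attachments = list(), related = list()) {
  eln_record_source(
    localId = "http://eln.example.org/notebook/5606/Spectrum_of_bromophenyl_dihydroindolone.html",
    title = "Spectrum of bromophenyl dihydroindolone",
    authors = list(c("Author", "A. Chemist"), c("PI", "F. Willoughby")),
    createdOn = as.Date("2013-08-01"),
    systemName = "OpenBlogELN", systemVersion = "2.3",
    attachments = attachments, relatedPublications = related,
    bodyMediaType = "text/html")
}

test_that("derivation maps source, config and user input onto the manifest", {
  src <- source_fixture(
    attachments = list(list(filename = "s.sdf",
                            mediaType = "chemical/x-mdl-sdfile",
                            description = "Structure file",
                            locator = "http://eln.example.org/files/s.sdf")),
    related = list(c("publication", "10.1186/1758-2946-5-52")))
  cfg <- fixture_site_config()
  m <- derive_manifest(src, cfg, eln_user_input("CC-BY-4.0", "P6M"))
  expect_identical(m$identifiers$primaryLocalIdentifier, src$localId)
  expect_identical(m$title, src$title)
  expect_identical(m$source, "OpenBlogELN/2.3")
  expect_identical(m$contact, cfg$contact)
  expect_identical(m$licensingBasis, "CC-BY-4.0")
  expect_identical(m$dates$creationDate, as.Date("2013-08-01"))
  expect_identical(m$dates$releaseDate,
                   compute_release_date(as.Date("2013-08-01"), "P6M"))
  expect_identical(length(m$content), 2L)  # body + one attachment
  expect_identical(m$content[[1]]$dataType, "text/html")
  expect_identical(m$content[[2]]$locator, "http://eln.example.org/files/s.sdf")
  expect_identical(m$relatedItems[[1]]$id, "10.1186/1758-2946-5-52")
  # config contributors merged with source authors, deduplicated on (role, name)
  keys <- vapply(m$contributors, function(co) paste(co$role, co$name),
                 character(1))
  expect_identical(anyDuplicated(keys), 0L)
  expect_true(all(c("PI F. Willoughby", "Author A. Chemist",
                    "Institution Example University") %in% keys))
  expect_identical(sum(keys == "PI F. Willoughby"), 1L)
  expect_true(validate_manifest(m)$valid)
})

test_that("attachment-free sources yield a single body content item", {
  m <- derive_manifest(source_fixture(), fixture_site_config())
  expect_identical(length(m$content), 1L)
  expect_identical(m$content[[1]]$dataType, "text/html")
})

test_that("zero embargo releases at creation; absent embargo leaves releaseDate absent", {
  src <- source_fixture()
  cfg <- fixture_site_config()
  m0 <- derive_manifest(src, cfg, eln_user_input(embargo = "P0D"))
  expect_identical(m0$dates$releaseDate, m0$dates$creationDate)
  m1 <- derive_manifest(src, cfg, eln_user_input())
  expect_null(m1$dates$releaseDate)
})

test_that("derivation errors on empty title/localId and missing contributors", {
  expect_error(eln_record_source("", "t", list(c("Author", "A")),
                                 Sys.Date(), "S", "1"), "localId")
  expect_error(eln_record_source("id", "", list(c("Author", "A")),
                                 Sys.Date(), "S", "1"), "title")
  expect_error(eln_site_config(eln_contact("EMail", "a@b.org"), list()),
               "contributor")
})

test_that("attachments without a usable media type get application/octet-stream with a warning", {
  src <- source_fixture(attachments = list(list(filename = "blob.bin",
                                                mediaType = NULL,
                                                description = "opaque blob")))
  expect_warning(m <- derive_manifest(src, fixture_site_config()),
                 "octet-stream")
  expect_identical(m$content[[2]]$dataType, "application/octet-stream")
})

test_that("derivation is deterministic and sound over the fixture population", {
  profile <- fixture_profile(seed = 55, nRecords = 25)
  cfg <- fixture_site_config()
  for (i in seq_len(25) - 1L) {
    src <- generate_record(profile, i)
    u <- generate_user_input(profile, i)
    m1 <- derive_manifest(src, cfg, u)
    m2 <- derive_manifest(src, cfg, u)
    expect_identical(m1, m2)
    expect_true(validate_manifest(m1)$valid, label = paste("record", i))
    expect_identical(length(m1$content), length(src$attachments) + 1L)
  }
})

test_that("site config files round-trip and enforce their invariants", {
  path <- withr::local_tempfile(fileext = ".cfg")
  cfg <- eln_site_config(
    eln_contact("EMail", "curator@example.org"),
    list(eln_contributor("Author", "A. Chemist",
                         c("https://orcid.org/0000-0001-0000-0002", "alt:1")),
         eln_contributor("PI", "F. Willoughby")))
  save_site_config(cfg, path)
  expect_identical(load_site_config(path), cfg)
  writeLines(c("contact.mode = EMail", "contact.value = a@b.org"), path)
  expect_error(load_site_config(path), "contributor")
  writeLines("garbage line without equals", path)
  expect_error(load_site_config(path), "parse")
  expect_error(load_site_config(file.path(tempdir(), "absent.cfg")), "exist")
})

test_that("source records round-trip through their JSON serialization", {
  path <- withr::local_tempfile(fileext = ".json")
  src <- source_fixture(
    attachments = list(list(filename = "s.sdf",
                            mediaType = "chemical/x-mdl-sdfile",
                            description = "Structure file",
                            locator = NULL)),
    related = list(c("publication", "10.1186/x")))
  write_record_json(src, path)
  back <- read_record_json(path)
  expect_identical(derive_manifest(back, fixture_site_config()),
                   derive_manifest(src, fixture_site_config()))
})
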