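test_that("a minimal mandatory-only manifest builds with optional fields absent", {
  m <- minimal_manifest()
  expect_s3_class(m, "eln_manifest")
  expect_identical(m$unitType, "Record")
  expect_null(m$keywords)
  expect_null(m$licensingBasis)
  expect_null(m$relatedItems)
  expect_null(m$identifiers$accessIdentifier)
  expect_null(m$dates$releaseDate)
})

test_that("unitType is a closed three-member enumeration", {
  base <- unclass(minimal_manifest())
  for (ut in c("Package", "Record", "Component")) {
    base$unitType <- ut
    m <- do.call(eln_manifest, base[!vapply(base, is.null, logical(1))])
    expect_identical(m$unitType, ut)
  }
  base$unitType <- "Experiment"
  expect_error(do.call(eln_manifest, base[!vapply(base, is.null, logical(1))]),
               "unitType")
})

test_that("every mandatory field is required and named in the error", {
  full <- unclass(complete_manifest())
  mandatory <- c("unitType", "title", "identifiers", "contact",
                 "contributors", "source", "dates", "content")
  for (f in mandatory) {
    args <- full
    args[[f]] <- NULL
    expect_error(do.call(eln_manifest, args[!vapply(args, is.null, logical(1))]),
                 regexp = f, ignore.case = TRUE, label = f)
  }
  # and removing any optional field still builds
  for (f in c("keywords", "licensingBasis", "relatedItems")) {
    args <- full
    args[[f]] <- NULL
    expect_s3_class(do.call(eln_manifest,
                            args[!vapply(args, is.null, logical(1))]),
                    "eln_manifest")
  }
})

test_that("subtype invariants reject malformed values with element paths", {
  expect_error(eln_identifier_set(""), "PrimaryLocalIdentifier")
  expect_error(eln_identifier_set("A", otherLocalIdentifiers = c("B", "A")),
               "OtherLocalIdentifier")
  expect_error(eln_identifier_set("A", accessIdentifier = "not a uri"),
               "AccessIdentifier")
  expect_error(eln_contact("EMail", "no-at-sign"), "e-mail")
  expect_error(eln_contact("EMail", "two@@example.org"), "e-mail")
  expect_error(eln_contact("SystemURI", "relative/path"), "URI")
  expect_s3_class(eln_contact("Instruction", "ask the PI via the front desk"),
                  "eln_contact")
  expect_error(eln_contact("Telephone", "x"), "mode")
  expect_error(eln_contributor("Author", ""), "Name")
  expect_error(eln_date_set(as.Date("2013-08-01"),
                            releaseDate = as.Date("2013-07-31")),
               "ReleaseDate")
  expect_error(eln_related_item("", "10.1/x"), "Relationship")
  expect_error(eln_content_item("body", "texthtml"), "DataType")
  expect_error(eln_content_item("body", "text/html", locator = "no scheme"),
               "Locator")
})

test_that("titles and keywords are trimmed; keywords deduplicated case-sensitively", {
  base <- unclass(minimal_manifest())
  base$title <- "  Workup of oxime  "
  base$keywords <- c(" NMR ", "NMR", "nmr", "", "IR")
  m <- do.call(eln_manifest, base[!vapply(base, is.null, logical(1))])
  expect_identical(m$title, "Workup of oxime")
  expect_identical(m$keywords, c("NMR", "nmr", "IR"))
})

test_that("manifest equality is structural", {
  expect_identical(complete_manifest(), complete_manifest())
  expect_identical(minimal_manifest(), minimal_manifest())
  expect_false(identical(minimal_manifest(), complete_manifest()))
})

test_that("ISO durations parse and negatives or time parts are rejected", {
  expect_identical(parse_iso_duration("P1Y2M3D"),
                   c(years = 1L, months = 2L, weeks = 0L, days = 3L))
  expect_identical(parse_iso_duration("P14D")[["days"]], 14L)
  expect_identical(parse_iso_duration("P2W")[["weeks"]], 2L)
  expect_error(parse_iso_duration("-P6M"), "negative")
  expect_error(parse_iso_duration("P-6M"), "negative")
  expect_error(parse_iso_duration("P"), "parse")
  expect_error(parse_iso_duration("PT6H"), "parse")
  expect_error(parse_iso_duration("6 months"), "parse")
})

test_that("release-date arithmetic matches frozen calendar cases", {
  expect_identical(compute_release_date(as.Date("2013-08-01"), "P0D"),
                   as.Date("2013-08-01"))
  expect_identical(compute_release_date(as.Date("2013-08-31"), "P6M"),
                   as.Date("2014-02-28"))
  expect_identical(compute_release_date(as.Date("2013-08-01"), "P1Y"),
                   as.Date("2014-08-01"))
  expect_identical(compute_release_date(as.Date("2012-01-31"), "P1M"),
                   as.Date("2012-02-29"))
  expect_identical(compute_release_date(as.Date("2013-01-31"), "P1M"),
                   as.Date("2013-02-28"))
  expect_identical(compute_release_date(as.Date("2013-08-01"), "P2W"),
                   as.Date("2013-08-15"))
})

test_that("release-date arithmetic agrees with the independent oracle on a random sweep", {
  set.seed(424242)
  for (i in 1:400) {
    base <- as.Date("2010-01-01") + sample(0:2500, 1)
    y <- sample(0:3, 1); mo <- sample(0:18, 1)
    w <- sample(0:4, 1); d <- sample(0:40, 1)
    dur <- sprintf("P%dY%dM%dW%dD", y, mo, w, d)
    expect_identical(compute_release_date(base, dur),
                     oracle_release_date(base, y, mo, w, d),
                     label = paste(base, dur))
  }
  # month-end clamping cases specifically
  for (day in c("2013-01-31", "2012-02-29", "2013-03-31", "2013-05-31")) {
    for (mo in 1:13) {
      expect_identical(compute_release_date(as.Date(day), sprintf("P%dM", mo)),
                       oracle_release_date(as.Date(day), 0L, mo, 0L, 0L))
    }
  }
})

test_that("release-date arithmetic is monotone in base and embargo", {
  set.seed(11)
  for (i in 1:60) {
    base <- as.Date("2012-01-01") + sample(0:1000, 1)
    mo <- sample(0:24, 1)
    d1 <- compute_release_date(base, sprintf("P%dM", mo))
    expect_gte(as.integer(compute_release_date(base + 1, sprintf("P%dM", mo)) - d1),
               0L)
    expect_gte(as.integer(compute_release_date(base, sprintf("P%dM", mo + 1)) - d1),
               0L)
    expect_gte(as.integer(d1 - base), 0L)
  }
})
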