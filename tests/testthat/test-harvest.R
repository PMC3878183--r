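today_fixture <- as.Date("2013-06-01")  # inside the fixture date range, so
                                        # some embargoes are still active

test_that("matching honours each constraint and an empty filter matches everything", {
  m <- complete_manifest()
  expect_true(manifest_matches(m, filter_spec(), today_fixture))
  expect_true(manifest_matches(m, filter_spec(mediaTypes = "chemical/x-mdl-sdfile"),
                               today_fixture))
  expect_false(manifest_matches(m, filter_spec(mediaTypes = "image/png"),
                                today_fixture))
  expect_true(manifest_matches(m, filter_spec(unitTypes = c("Record", "Package")),
                               today_fixture))
  expect_false(manifest_matches(m, filter_spec(unitTypes = "Component"),
                                today_fixture))
  expect_true(manifest_matches(m, filter_spec(keywordsAny = c("NMR", "zzz")),
                               today_fixture))
  expect_false(manifest_matches(m, filter_spec(keywordsAny = "nmr"),
                                today_fixture))  # case-sensitive
  # embargo: releaseDate 2014-02-01 is after today -> excluded when required
  expect_false(manifest_matches(m, filter_spec(requireReleased = TRUE),
                                today_fixture))
  expect_true(manifest_matches(m, filter_spec(requireReleased = TRUE),
                               as.Date("2014-02-01")))
  expect_true(manifest_matches(minimal_manifest(),
                               filter_spec(requireReleased = TRUE),
                               today_fixture))  # no releaseDate at all
  # license prefix is the one case-insensitive constraint
  expect_true(manifest_matches(m, filter_spec(licensePrefix = "cc-by"),
                               today_fixture))
  expect_false(manifest_matches(m, filter_spec(licensePrefix = "GPL"),
                                today_fixture))
  expect_false(manifest_matches(minimal_manifest(),
                                filter_spec(licensePrefix = "CC"),
                                today_fixture))  # no license recorded
})

test_that("match is monotone under filter relaxation", {
  store <- generate_store(fixture_profile(seed = 21, nRecords = 40))
  manifests <- lapply(store$entries, `[[`, "manifest")
  for (i in 1:15) {
    f <- random_filter(i, today_fixture)
    matched <- vapply(manifests, manifest_matches, logical(1), f, today_fixture)
    for (drop in c("unitTypes", "mediaTypes", "keywordsAny", "licensePrefix",
                   "requireReleased")) {
      g <- f
      g[[drop]] <- if (drop == "requireReleased") FALSE else NULL
      relaxed <- vapply(manifests, manifest_matches, logical(1), g,
                        today_fixture)
      expect_true(all(relaxed >= matched),
                  label = paste("filter", i, "minus", drop))
    }
  }
})

test_that("pagination partitions the matched set exactly as the naive scan", {
  store <- generate_store(fixture_profile(seed = 77, nRecords = 60))
  for (i in 1:25) {
    f <- random_filter(i, today_fixture)
    expected <- naive_scan(store, f, today_fixture)
    got <- harvest_all(store, f, pageSize = 7, today = today_fixture)
    expect_identical(got, expected, label = paste("filter", i))
    expect_identical(anyDuplicated(got), 0L)
  }
})

test_that("page arithmetic: 25 matches at page size 10 gives pages of 10, 10, 5", {
  store <- generate_store(fixture_profile(seed = 3, nRecords = 25))
  p1 <- list_manifests(store, filter_spec(), 10, today = today_fixture)
  expect_identical(nrow(p1$summaries), 10L)
  expect_false(is.null(p1$resumptionToken))
  p2 <- list_manifests(store, filter_spec(), 10, p1$resumptionToken,
                       today = today_fixture)
  expect_identical(nrow(p2$summaries), 10L)
  p3 <- list_manifests(store, filter_spec(), 10, p2$resumptionToken,
                       today = today_fixture)
  expect_identical(nrow(p3$summaries), 5L)
  expect_null(p3$resumptionToken)
  expect_identical(anyDuplicated(c(p1$storeIds, p2$storeIds, p3$storeIds)), 0L)
})

test_that("empty stores give an empty page and no token; bad tokens error", {
  p <- list_manifests(manifest_store(), filter_spec(), 10)
  expect_identical(nrow(p$summaries), 0L)
  expect_null(p$resumptionToken)
  store <- generate_store(fixture_profile(seed = 3, nRecords = 25))
  expect_error(list_manifests(store, filter_spec(), 10, "not-a-token"),
               "token")
  # a token issued under one filter is rejected under another
  tok <- list_manifests(store, filter_spec(), 10,
                        today = today_fixture)$resumptionToken
  expect_error(list_manifests(store, filter_spec(unitTypes = "Record"), 10,
                              tok, today = today_fixture), "token")
  expect_error(list_manifests(store, filter_spec(), 0), "positive")
})

test_that("directory-backed stores round-trip manifests and feed identically", {
  dir <- withr::local_tempdir()
  store <- generate_store(fixture_profile(seed = 9, nRecords = 12))
  write_store(store, dir)
  expect_identical(length(list.files(dir, pattern = "\\.xml$")), 12L)
  back <- read_store(dir)
  expect_identical(lapply(back$entries, `[[`, "manifest"),
                   lapply(store$entries, `[[`, "manifest"))
  f <- filter_spec(mediaTypes = "image/png")
  expect_identical(harvest_all(back, f, 5, today = today_fixture),
                   harvest_all(store, f, 5, today = today_fixture))
})

test_that("tier resolution projects onto knowledge, information and processing layers", {
  m <- complete_manifest()
  info <- resolve_tier(m, "information")
  expect_identical(info, m$relatedItems)
  proc <- resolve_tier(m, "processing")
  expect_identical(proc$content, m$content)
  expect_identical(proc$accessIdentifier, "http://data.example.org/eln/1042")
  kn <- resolve_tier(m, "knowledge")
  expect_s3_class(kn, "eln_manifest")
  expect_null(kn$relatedItems)
  expect_true(all(vapply(kn$content, function(ci) is.null(ci$locator),
                         logical(1))))
  expect_true(validate_manifest(kn)$valid)
  # descriptive core untouched
  expect_identical(kn$title, m$title)
  expect_identical(kn$identifiers, m$identifiers)
  expect_identical(kn$contributors, m$contributors)
  expect_error(resolve_tier(m, "detail"), "knowledge, information, processing")
})

test_that("information and processing views are disjoint and manifests without related items give an empty information layer", {
  m <- complete_manifest()
  info_ids <- vapply(resolve_tier(m, "information"), `[[`, character(1), "id")
  proc <- resolve_tier(m, "processing")
  proc_vals <- c(vapply(proc$content, `[[`, character(1), "description"),
                 proc$accessIdentifier)
  expect_length(intersect(info_ids, proc_vals), 0)
  expect_identical(resolve_tier(minimal_manifest(), "information"), list())
  expect_null(resolve_tier(minimal_manifest(), "processing")$accessIdentifier)
})

test_that("knowledge-tier crosswalk agrees with the full crosswalk on every element but relation", {
  profile <- fixture_profile(seed = 41, nRecords = 20)
  for (i in seq_len(20) - 1L) {
    m <- generate_manifest(profile, i)
    dc_full <- dc_crosswalk(m)
    dc_kn <- dc_crosswalk(resolve_tier(m, "knowledge"))
    expect_identical(dc_kn, dc_full[dc_full$element != "relation", ,
                                    drop = FALSE] |>
                       (\(d) { rownames(d) <- NULL; d })())
    if (is.null(m$relatedItems))
      expect_identical(dc_kn, dc_full)
  }
})
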