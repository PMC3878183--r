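test_that("generation is fully deterministic in (seed, index)", {
  p <- fixture_profile(seed = 123, nRecords = 20)
  expect_identical(generate_record(p, 7), generate_record(p, 7))
  expect_identical(generate_manifest(p, 7), generate_manifest(p, 7))
  expect_identical(generate_user_input(p, 7), generate_user_input(p, 7))
  expect_identical(generate_store(p), generate_store(p))
  expect_identical(generate_molfile(5, 12), generate_molfile(5, 12))
  # independent of generation order and of the global RNG state
  set.seed(1); a <- generate_record(p, 3)
  set.seed(999); invisible(generate_record(p, 9)); b <- generate_record(p, 3)
  expect_identical(a, b)
  # different seeds diverge
  expect_false(identical(generate_record(fixture_profile(seed = 124), 7),
                         generate_record(p, 7)))
})

test_that("degenerate profiles behave: zero attachment rates, zero records, bad index", {
  p0 <- fixture_profile(seed = 1, nRecords = 10,
                        attachmentRate = c("image/png" = 0, "text/csv" = 0))
  for (i in 0:9)
    expect_length(generate_record(p0, i)$attachments, 0)
  empty <- fixture_profile(seed = 1, nRecords = 0)
  expect_length(generate_store(empty)$entries, 0)
  expect_error(generate_record(p0, 10), "outside")
  expect_error(generate_record(p0, -1), "outside")
  expect_error(fixture_profile(embargoRate = 1.5), "probabilit")
  expect_error(fixture_profile(dateRange = as.Date(c("2014-01-01",
                                                     "2012-01-01"))), "end")
})

test_that("embargo frequency stays within 3 binomial standard deviations of its rate", {
  p <- fixture_profile(seed = 2024, nRecords = 1000, embargoRate = 0.3)
  hits <- sum(vapply(seq_len(1000) - 1L, function(i)
    !is.null(generate_user_input(p, i)$embargo), logical(1)))
  sd3 <- 3 * sqrt(1000 * 0.3 * 0.7)  # ~43.5
  expect_lt(abs(hits - 300), sd3)
})

test_that("generated stores derive and validate cleanly", {
  store <- generate_store(fixture_profile(seed = 88, nRecords = 10))
  expect_length(store$entries, 10)
  for (e in store$entries) {
    expect_true(validate_xml(manifest_to_xml(e$manifest)),
                label = paste("schema validity of", e$storeId))
    expect_true(validate_manifest(e$manifest)$valid)
  }
})

test_that("the default profile exercises every optional manifest field somewhere", {
  p <- fixture_profile(seed = 1)
  manifests <- lapply(seq_len(p$nRecords) - 1L, generate_manifest, profile = p)
  has <- function(f) any(vapply(manifests, function(m) !is.null(m[[f]]),
                                logical(1)))
  expect_true(has("keywords"))
  expect_true(has("licensingBasis"))
  expect_true(has("relatedItems"))
  expect_true(any(vapply(manifests, function(m)
    !is.null(m$identifiers$accessIdentifier), logical(1))))
  expect_true(any(vapply(manifests, function(m)
    length(m$identifiers$otherLocalIdentifiers) > 0, logical(1))))
  for (d in c("releaseDate", "publicationDate", "submissionDate"))
    expect_true(any(vapply(manifests, function(m) !is.null(m$dates[[d]]),
                           logical(1))), label = d)
  expect_true(any(vapply(manifests, function(m)
    any(vapply(m$content, function(ci) !is.null(ci$locator), logical(1))),
    logical(1))))
})

test_that("generated molfiles are structurally correct V2000 chains", {
  mol1 <- generate_molfile(1, 1)
  lines1 <- strsplit(mol1, "\n")[[1]]
  expect_true(startsWith(lines1[4], "  1  0"))
  mol5 <- generate_molfile(1, 5)
  lines5 <- strsplit(mol5, "\n")[[1]]
  expect_true(startsWith(lines5[4], "  5  4"))
  atom_block <- lines5[5:9]
  expect_true(all(grepl(" [CNO]  ", atom_block)))
  bond_block <- lines5[10:13]
  expect_length(bond_block, 4)
  expect_identical(lines5[length(lines5)], "M  END")
  expect_error(generate_molfile(1, 0), "between")
  expect_error(generate_molfile(1, 100), "between")
})

test_that("molfiles from a 100-seed sweep all pass the packaging counts-line check", {
  m <- minimal_manifest()
  for (s in 1:100) {
    n <- 1L + (s %% 30L)
    pkg <- package_deposition(list(generate_molfile(s, n)), m, "E-1")
    expect_identical(length(split_deposition(pkg)$structures), 1L,
                     label = paste("seed", s))
  }
})

test_that("a written fixture corpus is complete and re-readable", {
  dir <- withr::local_tempdir()
  p <- fixture_profile(seed = 6, nRecords = 4)
  write_fixture_corpus(p, dir)
  expect_length(list.files(dir, pattern = "^record-.*\\.json$"), 4)
  expect_length(list.files(dir, pattern = "^manifest-.*\\.xml$"), 4)
  expect_length(list.files(dir, pattern = "^structure-.*\\.mol$"), 4)
  src <- read_record_json(file.path(dir, "record-0002.json"))
  expect_identical(src, generate_record(p, 2))
  m <- read_manifest(file.path(dir, "manifest-0002.xml"))
  expect_identical(m, derive_manifest(src, fixture_site_config(),
                                      generate_user_input(p, 2)))
})
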