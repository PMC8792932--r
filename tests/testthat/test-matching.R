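# Matching engine: property extraction, full-match regex semantics,
# run-item matching, document-order scan, and template narrowing.

make_session <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  t1 <- write_toy(file.path(dir, "raw", "sub-001", "007-t1", "a_01.toy"),
                  header = list(ProtocolName = "t1_mprage_sag_p2_iso_1.0",
                                SeriesNumber = 7, SeriesDescription = "t1",
                                ImageTypeText = "M",
                                PatientComments = "pilot"))
  write_toy(file.path(dir, "raw", "sub-001", "007-t1", "a_02.toy"),
            header = list(ProtocolName = "t1_mprage_sag_p2_iso_1.0",
                          SeriesNumber = 7))
  write_toy(file.path(dir, "raw", "sub-001", "007-t1", "a_03.toy"),
            header = list(ProtocolName = "t1_mprage_sag_p2_iso_1.0",
                          SeriesNumber = 7))
  list(dir = dir, t1 = t1)
}

test_that("extract_property covers the four property keys only", {
  fx <- make_session()
  src <- data_source(fx$t1)
  expect_equal(extract_property(src, "filename"), "a_01.toy")
  expect_false(grepl("\\\\", extract_property(src, "filepath")))
  expect_true(endsWith(extract_property(src, "filepath"), "007-t1/a_01.toy"))
  expect_equal(extract_property(src, "filesize"),
               as.character(file.size(fx$t1)))
  expect_equal(extract_property(src, "nrfiles"), "3")
  expect_error(extract_property(src, "filecolor"),
               "unknown property key 'filecolor'.*filepath")
})

test_that("match_value uses whole-value regex semantics", {
  expect_true(match_value(".*(mprage|T1w).*", "t1_mprage_sag_p2_iso_1.0"))
  expect_true(match_value("", "anything"))
  expect_true(match_value(NULL, "anything"))
  expect_false(match_value("T1w", "T1w_extra"))
  expect_true(match_value("T1w", "T1w"))
  expect_false(match_value(".*\\.IMA", "file.toy"))
  expect_true(match_value("[0-9]+", 42))
  expect_error(match_value("(", "x"), "invalid regular expression")
})

test_that("match_value agrees with an independent full-span oracle", {
  set.seed(11)
  patterns <- random_pattern_pool()
  values <- c("t1_mprage_sag", "localizer", "M", "P", "xxx", "xx",
              "field_map_2p4iso", "abc123", "", "T1w_extra")
  for (p in patterns) {
    for (v in values) {
      expect_identical(match_value(p, v), oracle_match_value(p, v),
                       label = sprintf("pattern '%s' vs '%s'", p, v))
    }
  }
})

test_that("match_run requires all non-empty filters to hold", {
  fx <- make_session()
  src <- data_source(fx$t1)
  t1_run <- run_item(attributes = list(ProtocolName = ".*(mprage|T1w).*"),
                     bids = list(suffix = "T1w"))
  expect_true(match_run(src, t1_run))
  # filename filter that cannot match
  expect_false(match_run(src, run_item(
    properties = list(filename = ".*\\.IMA"),
    attributes = list(ProtocolName = ".*(mprage|T1w).*"),
    bids = list(suffix = "T1w"))))
  # catch-all with all-empty patterns
  expect_true(match_run(src, run_item(bids = list(suffix = "x"))))
  # a non-empty pattern over an absent attribute fails
  expect_false(match_run(src, run_item(
    attributes = list(MissingKey = ".+"), bids = list(suffix = "x"))))
})

test_that("find_run_match takes the first match in document order", {
  fx <- make_session()
  tpl <- builtin_template()
  loc <- write_toy(file.path(fx$dir, "raw", "sub-001", "001-loc", "l_01.toy"),
                   header = list(ProtocolName = "localizer_32ch-head",
                                 SeriesNumber = 1))
  odd <- write_toy(file.path(fx$dir, "raw", "sub-001", "090-odd", "o_01.toy"),
                   header = list(ProtocolName = "weird_special_seq",
                                 SeriesNumber = 90, SeriesDescription = "odd"))
  expect_equal(find_run_match(data_source(loc), tpl)$datatype, "exclude")
  expect_equal(find_run_match(data_source(fx$t1), tpl)$datatype, "anat")
  expect_equal(find_run_match(data_source(odd), tpl)$datatype, "extra_data")
  # a source format without a section is an error
  broken <- structure(list(Options = tpl$Options), class = "bidsmap")
  expect_error(find_run_match(data_source(fx$t1), broken), "no section")
})

test_that("find_run_match equals the brute-force first-match oracle", {
  set.seed(101)
  for (rep in 1:200) {
    root <- tempfile("matchprop")
    dir.create(root, recursive = TRUE)
    sesdir <- random_toy_tree(root, n_files = 3)
    map <- random_bidsmap()
    samples <- collect_samples(sesdir)
    for (src in samples) {
      got <- find_run_match(src, map)
      want <- oracle_first_match(src, map)
      expect_identical(got$datatype, want$datatype,
                       label = sprintf("rep %d, %s", rep, src$path))
      expect_identical(got$index, want$index,
                       label = sprintf("rep %d index, %s", rep, src$path))
    }
    unlink(root, recursive = TRUE)
  }
})

test_that("expand_template_run narrows patterns to literal header text", {
  fx <- make_session()
  src <- data_source(fx$t1)
  tpl <- builtin_template()
  m <- find_run_match(src, tpl)
  run <- expand_template_run(m$run, src)
  # matched attribute patterns become the literal header value
  expect_equal(run$attributes$ProtocolName, "t1_mprage_sag_p2_iso_1.0")
  expect_false(grepl("[|]|\\.\\*", run$attributes$ProtocolName))
  # empty attribute patterns stay empty; property patterns stay verbatim
  expect_equal(run$attributes$SeriesDescription, "")
  expect_equal(run$properties$filename, "")
  # mapping-time dynamics resolve, coining-time dynamics survive
  expect_equal(run$bids$acq, "t1mpragesagp2iso10")
  expect_equal(run$bids$run, "<<1>>")
  expect_equal(run$meta$Comments, "<<PatientComments>>")
  expect_equal(run$provenance, src$path)
})

test_that("narrowing is sound: the expanded run still matches its source", {
  set.seed(202)
  for (rep in 1:25) {
    root <- tempfile("narrow")
    dir.create(root, recursive = TRUE)
    sesdir <- random_toy_tree(root, n_files = 3)
    map <- random_bidsmap()
    for (src in collect_samples(sesdir)) {
      m <- find_run_match(src, map)
      run <- expand_template_run(m$run, src)
      expect_true(match_run(src, run), label = src$path)
    }
    unlink(root, recursive = TRUE)
  }
})
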