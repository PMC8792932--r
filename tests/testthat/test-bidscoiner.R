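# Conversion: output naming, run indices, sidecars, IntendedFor,
# scaffolding, skipping, and additive safety.

coin_ready_study <- function(env = parent.frame(), n_subjects = 1) {
  fx <- local_example_study(env = env, n_subjects = n_subjects)
  study <- run_bidsmapper(fx$raw, fx$bids, quiet = TRUE)
  study <- example_study_edits(study)
  save_bidsmap(study, study_bidsmap_path(fx$bids))
  fx
}

test_that("coining the example study writes the expected BIDS tree", {
  fx <- coin_ready_study()
  report <- run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  expect_equal(report$subjects$status, "processed")
  imaging <- list.files(fx$bids, pattern = "\\.nii\\.gz$", recursive = TRUE)
  expect_length(imaging, 11)   # 1 anat + 6 func + 4 fmap; localizers excluded
  expect_setequal(
    basename(imaging)[grepl("/func/", imaging)],
    c("sub-001_task-Reward_acq-mb8_run-1_sbref.nii.gz",
      "sub-001_task-Reward_acq-mb8_run-1_bold.nii.gz",
      "sub-001_task-Stop_acq-mb3me3_run-1_sbref.nii.gz",
      "sub-001_task-Stop_acq-mb3me3_run-1_echo-1_bold.nii.gz",
      "sub-001_task-Stop_acq-mb3me3_run-1_echo-2_bold.nii.gz",
      "sub-001_task-Stop_acq-mb3me3_run-1_echo-3_bold.nii.gz"))
  expect_true(any(grepl("anat/sub-001_acq-mprage_run-1_T1w", imaging)))
  # every imaging file has a valid-JSON sidecar
  for (img in imaging) {
    sidecar <- file.path(fx$bids, sub("\\.nii\\.gz$", ".json", img))
    expect_true(file.exists(sidecar))
    expect_silent(jsonlite::read_json(sidecar))
  }
  # nothing from the excluded localizers
  expect_false(any(grepl("localizer|Scout", imaging, ignore.case = TRUE)))
})

test_that("every written imaging name passes schema validation", {
  fx <- coin_ready_study()
  run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  imaging <- list.files(fx$bids, pattern = "\\.nii\\.gz$", recursive = TRUE)
  for (img in imaging) {
    dt <- basename(dirname(img))
    name <- sub("\\.nii\\.gz$", "", basename(img))
    parsed <- parse_bidsname(name)
    run <- run_item(bids = c(as.list(parsed$entities),
                             list(suffix = parsed$suffix)))
    expect_length(validate_run(run, dt), 0)
  }
})

test_that("fieldmap sidecars point IntendedFor at files that exist", {
  fx <- coin_ready_study()
  run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  fmaps <- list.files(file.path(fx$bids, "sub-001", "fmap"),
                      pattern = "\\.json$", full.names = TRUE)
  expect_length(fmaps, 4)
  for (sc in fmaps) {
    meta <- jsonlite::read_json(sc)
    expect_true(!is.null(meta$IntendedFor))
    targets <- unlist(meta$IntendedFor)
    expect_gt(length(targets), 0)
    task <- if (grepl("2p4", sc)) "Reward" else "Stop"
    expect_true(all(grepl(task, basename(targets))))
    for (t in targets) {
      expect_true(file.exists(file.path(fx$bids, "sub-001", t)), label = t)
    }
  }
})

test_that("sidecar merging applies user meta and anonymization", {
  dir <- withr::local_tempdir()
  path <- write_toy(file.path(dir, "sub-001", "001-s", "a.toy"),
                    header = list(ProtocolName = "x", SeriesNumber = 1,
                                  EchoTime = "0.0125",
                                  PatientComments = "pilot",
                                  AcquisitionDate = "20211207",
                                  Age = "31.7"))
  src <- data_source(path)
  plugin_meta <- bidsforge:::toy_sidecar_meta(path)
  # standard fields survive an empty user dict
  merged <- merge_sidecar(plugin_meta, list(), src)
  expect_equal(merged$EchoTime, 0.0125)
  expect_equal(merged$AcquisitionDate, "20211207")
  # user values resolve dynamics and overwrite/append
  merged <- merge_sidecar(plugin_meta,
                          list(Comments = "<<PatientComments>>",
                               EchoTime = "0.5"), src)
  expect_equal(merged$Comments, "pilot")
  expect_equal(merged$EchoTime, 0.5)
  # keys resolving to empty text are omitted
  merged <- merge_sidecar(plugin_meta, list(Gone = ""), src)
  expect_false("Gone" %in% names(merged))
  # anonymization floors the age and discards the acquisition date
  merged <- merge_sidecar(plugin_meta, list(), src, anon = TRUE)
  expect_equal(merged$Age, 31)
  expect_false("AcquisitionDate" %in% names(merged))
  # identifying header fields never reach the sidecar
  expect_false(any(c("PatientName", "PatientComments", "Sex") %in%
                     names(plugin_meta)))
})

test_that("run indices increment until free", {
  dir <- withr::local_tempdir()
  name <- "sub-001_acq-mprage_run-<<1>>_T1w"
  expect_equal(assign_run_index(dir, name), "sub-001_acq-mprage_run-1_T1w")
  file.create(file.path(dir, "sub-001_acq-mprage_run-1_T1w.nii.gz"))
  expect_equal(assign_run_index(dir, name), "sub-001_acq-mprage_run-2_T1w")
  file.create(file.path(dir, "sub-001_acq-mprage_run-2_T1w.nii.gz"))
  expect_equal(assign_run_index(dir, name), "sub-001_acq-mprage_run-3_T1w")
  # a name without a dynamic run passes through
  expect_equal(assign_run_index(dir, "sub-001_T1w"), "sub-001_T1w")
  # seeds above 1 start there
  expect_equal(assign_run_index(dir, "sub-001_acq-x_run-<<4>>_T1w"),
               "sub-001_acq-x_run-4_T1w")
})

test_that("run-index assignment agrees with an increment-until-free oracle", {
  set.seed(77)
  for (rep in 1:25) {
    dir <- tempfile("runs")
    dir.create(dir)
    taken <- sample(1:8, sample(0:5, 1))
    for (r in taken) {
      file.create(file.path(dir, sprintf("sub-001_run-%d_T1w.nii.gz", r)))
    }
    seed <- sample(1:3, 1)
    got <- assign_run_index(dir, sprintf("sub-001_run-<<%d>>_T1w", seed))
    want <- seed
    while (want %in% taken) want <- want + 1
    expect_equal(got, sprintf("sub-001_run-%d_T1w", want),
                 label = paste("taken:", paste(taken, collapse = ",")))
    unlink(dir, recursive = TRUE)
  }
})

test_that("IntendedFor wildcards select the matching imaging files", {
  dir <- withr::local_tempdir()
  subj <- file.path(dir, "sub-001")
  files <- c("func/sub-001_task-Stop1Go_bold.nii.gz",
             "func/sub-001_task-Stop2Go_bold.nii.gz",
             "func/sub-001_task-Reward_bold.nii.gz",
             "func/sub-001_task-Reward_sbref.nii.gz",
             "anat/sub-001_T1w.nii.gz")
  for (f in files) {
    dir.create(file.path(subj, dirname(f)), recursive = TRUE,
               showWarnings = FALSE)
    file.create(file.path(subj, f))
  }
  # all functional runs carry "task" in their name
  expect_setequal(resolve_intendedfor("<<task>>", subj), files[1:4])
  # multiple patterns union
  expect_setequal(resolve_intendedfor("<<Stop*Go><Reward>>", subj), files[1:4])
  expect_setequal(resolve_intendedfor("<<Stop1Go>>", subj), files[1])
  # no match yields an empty set (caller omits the field with a warning)
  expect_length(resolve_intendedfor("<<Nothing>>", subj), 0)
  # session scoping
  ses <- file.path(dir, "sub-002", "ses-01", "func")
  dir.create(ses, recursive = TRUE)
  file.create(file.path(ses, "sub-002_ses-01_task-Go_bold.nii.gz"))
  expect_equal(resolve_intendedfor("<<task>>", file.path(dir, "sub-002"), "01"),
               "ses-01/func/sub-002_ses-01_task-Go_bold.nii.gz")
})

test_that("scaffolding creates placeholders once and never overwrites", {
  dir <- withr::local_tempdir()
  bids <- file.path(dir, "bids")
  scaffold_dataset(bids)
  expect_true(file.exists(file.path(bids, "dataset_description.json")))
  expect_true(file.exists(file.path(bids, "README")))
  expect_true(file.exists(file.path(bids, ".bidsignore")))
  expect_true(file.exists(file.path(bids, "participants.tsv")))
  expect_true("extra_data/" %in% readLines(file.path(bids, ".bidsignore")))
  dd <- jsonlite::read_json(file.path(bids, "dataset_description.json"))
  expect_equal(dd$BIDSVersion, "1.6.0")
  # user content survives re-scaffolding
  writeLines("My own readme.", file.path(bids, "README"))
  scaffold_dataset(bids)
  expect_equal(readLines(file.path(bids, "README")), "My own readme.")
})

test_that("subjects with existing output are skipped unless forced", {
  fx <- coin_ready_study(n_subjects = 2)
  r1 <- run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  expect_equal(sort(r1$subjects$status), c("processed", "processed"))
  before <- tree_hash(fx$bids, data_only = TRUE)

  # plain re-run: everything skipped, tree untouched
  r2 <- run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  expect_equal(r2$subjects$status, c("skipped", "skipped"))
  expect_equal(nrow(r2$files), 0)
  expect_identical(tree_hash(fx$bids, data_only = TRUE), before)

  # an explicit participant implies force for that subject only
  r3 <- run_bidscoiner(fx$raw, fx$bids, participants = "sub-001",
                       quiet = TRUE)
  expect_equal(r3$subjects$status[r3$subjects$subject == "sub-001"],
               "processed")
  expect_equal(r3$subjects$status[r3$subjects$subject == "sub-002"],
               "skipped")
  expect_gt(nrow(r3$files), 0)
})

test_that("coining is additive: no pre-existing file is removed or truncated", {
  fx <- coin_ready_study()
  marker <- file.path(fx$bids, "derivatives", "note.txt")
  dir.create(dirname(marker), recursive = TRUE)
  writeLines("pre-existing analysis output", marker)
  before <- tree_hash(fx$bids)
  run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  after <- tree_hash(fx$bids)
  expect_length(setdiff(names(before), names(after)), 0)
  common <- intersect(names(before), names(after))
  common <- common[!grepl("\\.(log|errors)$", common)]
  expect_identical(after[common], before[common])
  expect_equal(readLines(marker), "pre-existing analysis output")
})

test_that("coining without a study map is a clear error", {
  fx <- local_example_study()
  expect_error(run_bidscoiner(fx$raw, fx$bids), "study bidsmap not found")
})

test_that("coining refuses a study map with red run-items", {
  fx <- coin_ready_study()
  study <- load_bidsmap(study_bidsmap_path(fx$bids), quiet = TRUE)
  study <- edit_run_items(study, "Toy",
                          where = function(run) run$datatype == "func",
                          bids = list(task = ""))
  save_bidsmap(study, study_bidsmap_path(fx$bids))
  err <- expect_error(run_bidscoiner(fx$raw, fx$bids, quiet = TRUE),
                      "invalid \\(red\\) run-items")
  expect_match(conditionMessage(err), "required entity 'task'")
})

test_that("participants.tsv gains one row per converted subject", {
  fx <- coin_ready_study(n_subjects = 2)
  run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  tab <- utils::read.delim(file.path(fx$bids, "participants.tsv"))
  expect_equal(tab$participant_id, c("sub-001", "sub-002"))
  expect_equal(tab$sex, c("M", "F"))
  expect_equal(tab$age, c(31, 32))   # anonymized: floored
  # re-running never duplicates rows
  run_bidscoiner(fx$raw, fx$bids, force = TRUE, quiet = TRUE)
  tab2 <- utils::read.delim(file.path(fx$bids, "participants.tsv"))
  expect_equal(nrow(tab2), 2)
})

test_that("logs mirror events and a clean run adds no errors", {
  fx <- coin_ready_study()
  run_bidscoiner(fx$raw, fx$bids, quiet = TRUE)
  logdir <- file.path(fx$bids, "code", "bidscoin")
  expect_true(file.exists(file.path(logdir, "bidscoiner.log")))
  errfile <- file.path(logdir, "bidscoiner.errors")
  expect_true(file.exists(errfile))
  expect_length(readLines(errfile, warn = FALSE), 0)
  n_log <- length(readLines(file.path(logdir, "bidscoiner.log")))
  # a stray unmatched file produces a warning routed to both files
  write_toy(file.path(fx$raw, "sub-001", "091-odd", "091_01.toy"),
            header = list(ProtocolName = "mystery_sequence",
                          SeriesNumber = 91, SeriesDescription = "odd",
                          ImageTypeText = "M"))
  run_bidscoiner(fx$raw, fx$bids, force = TRUE, quiet = TRUE)
  expect_gt(length(readLines(errfile, warn = FALSE)), 0)
  expect_true(any(grepl("no study mapping", readLines(errfile, warn = FALSE))))
  # append mode: the log keeps both runs in order
  expect_gt(length(readLines(file.path(logdir, "bidscoiner.log"))), n_log)
})
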