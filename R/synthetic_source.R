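# Deterministic synthetic raw data in the toy scan format.
#
# The generated dataset mirrors a standard task-fMRI acquisition: two
# localizer/scout series, an MPRAGE T1w, a multiband single-band-reference
# + bold pair, a multi-echo single-band-reference + bold pair (three
# echoes), and two fieldmap magnitude/phasediff pairs (one per functional
# resolution). Series numbering (gaps included) follows the scanner's
# bookkeeping so folder names stay citable. One designated subject is
# written FLAT — all series' files in one folder — to exercise discovery
# over unsorted exports.

toy_protocols <- function() {
  list(
    list(series = 1L,  protocol = "localizer_32ch-head",              files = 3L, type = "M", echo_time = 0.004,   payload = 4L),
    list(series = 2L,  protocol = "AAHead_Scout_32ch-head",           files = 5L, type = "M", echo_time = 0.0016,  payload = 4L),
    list(series = 7L,  protocol = "t1_mprage_sag_ipat2_1p0iso",       files = 4L, type = "M", echo_time = 0.00226, payload = 8L),
    list(series = 47L, protocol = "cmrr_2p4iso_mb8_TR0700_SBRef",     files = 1L, type = "M", echo_time = 0.039,   payload = 6L),
    list(series = 48L, protocol = "cmrr_2p4iso_mb8_TR0700",           files = 5L, type = "M", echo_time = 0.039,   payload = 6L),
    list(series = 49L, protocol = "field_map_2p4iso",                 files = 2L, type = "M", echo_time = c(0.00492, 0.00738), payload = 5L),
    list(series = 50L, protocol = "field_map_2p4iso",                 files = 1L, type = "P", echo_time = 0.00738, payload = 5L),
    list(series = 59L, protocol = "cmrr_2p5iso_mb3me3_TR1500_SBRef",  files = 1L, type = "M", echo_time = 0.014,   payload = 6L),
    list(series = 60L, protocol = "cmrr_2p5iso_mb3me3_TR1500",        files = 3L, type = "M", echo_time = c(0.014, 0.0352, 0.0564), echoes = 3L, payload = 6L),
    list(series = 61L, protocol = "field_map_2p5iso",                 files = 2L, type = "M", echo_time = c(0.0047, 0.00716), payload = 5L),
    list(series = 62L, protocol = "field_map_2p5iso",                 files = 1L, type = "P", echo_time = 0.00716, payload = 5L)
  )
}

toy_header_lines <- function(proto, subject_label, echo = NULL, echo_time,
                             acq_date) {
  lines <- c(
    paste0("ProtocolName: ", proto$protocol),
    paste0("SeriesNumber: ", proto$series),
    paste0("SeriesDescription: ", proto$protocol),
    paste0("ImageTypeText: ", proto$type)
  )
  if (!is.null(echo)) lines <- c(lines, paste0("EchoNumber: ", echo))
  lines <- c(
    lines,
    paste0("EchoTime: ", format(echo_time, scientific = FALSE)),
    paste0("PatientName: ID_", subject_label, "_anon"),
    "PatientComments: synthetic phantom acquisition",
    paste0("AcquisitionDate: ", acq_date),
    paste0("Sex: ", if (as.integer(subject_label) %% 2L == 1L) "M" else "F"),
    paste0("Age: ", format(30 + as.integer(subject_label) + 0.7, nsmall = 1))
  )
  lines
}

random_payload <- function(n_lines) {
  pool <- c(letters, LETTERS, 0:9)
  vapply(seq_len(n_lines), function(i) {
    paste0(sample(pool, 40L, replace = TRUE), collapse = "")
  }, character(1))
}

write_toy_file <- function(path, proto, subject_label, echo, echo_time,
                           acq_date) {
  lines <- c(TOY_MAGIC,
             toy_header_lines(proto, subject_label, echo, echo_time, acq_date),
             "---",
             random_payload(proto$payload))
  writeLines(lines, path)
}

#' Generate a deterministic synthetic raw dataset
#'
#' Writes `n_subjects` subjects, each with the same eleven acquisition
#' series (see the package vignette). The same seed always produces a
#' byte-identical tree. The subject numbered `flat_subject` (when it
#' exists) is written without series subfolders.
#'
#' @param outdir Raw output folder (created; must be empty unless
#'   `overwrite`).
#' @param n_subjects Number of subjects (>= 0).
#' @param with_sessions Add a `ses-01` folder level.
#' @param seed Integer seed driving the payload bytes.
#' @param flat_subject Subject number to emit flat (default 2; use 0 for
#'   none).
#' @param overwrite Replace an existing non-empty `outdir`.
#' @return `outdir`, invisibly.
#' @export
generate_raw_dataset <- function(outdir, n_subjects = 1L, with_sessions = FALSE,
                                 seed = 0L, flat_subject = 2L,
                                 overwrite = FALSE) {
  stopifnot(n_subjects >= 0L)
  if (dir.exists(outdir) && length(list.files(outdir, all.files = TRUE,
                                              no.. = TRUE))) {
    if (!overwrite) {
      stop(sprintf("output folder '%s' exists and is not empty", outdir),
           call. = FALSE)
    }
    unlink(outdir, recursive = TRUE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (n_subjects == 0L) return(invisible(outdir))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (s in seq_len(n_subjects)) {
    label <- sprintf("%03d", s)
    subdir <- file.path(outdir, paste0("sub-", label))
    sesdir <- if (with_sessions) file.path(subdir, "ses-01") else subdir
    flat <- s == flat_subject
    acq_date <- sprintf("202112%02d", (s %% 27L) + 1L)
    for (proto in toy_protocols()) {
      series_dir <- if (flat) sesdir else
        file.path(sesdir, sprintf("%03d-%s", proto$series, proto$protocol))
      dir.create(series_dir, recursive = TRUE, showWarnings = FALSE)
      echoes <- proto$echoes %||% 0L
      if (echoes > 0L) {
        for (e in seq_len(echoes)) {
          for (f in seq_len(proto$files)) {
            path <- file.path(series_dir,
                              sprintf("%03d_e%d_%02d.toy", proto$series, e, f))
            write_toy_file(path, proto, label, e, proto$echo_time[e], acq_date)
          }
        }
      } else {
        for (f in seq_len(proto$files)) {
          et <- proto$echo_time[((f - 1L) %% length(proto$echo_time)) + 1L]
          path <- file.path(series_dir,
                            sprintf("%03d_%02d.toy", proto$series, f))
          write_toy_file(path, proto, label, NULL, et, acq_date)
        }
      }
    }
  }
  invisible(outdir)
}

#' Apply the curation edits for the generated example study
#'
#' The programmatic counterpart of cleaning up a freshly discovered study
#' map before coining: readable task labels (`Reward` for the multiband
#' protocol, `Stop` for the multi-echo protocol), short acquisition
#' labels, fieldmap IntendedFor patterns targeting their own functional
#' runs, and no session level in the output names.
#'
#' @param study_map The study bidsmap produced by [run_bidsmapper()] on a
#'   generated dataset.
#' @return The edited bidsmap.
#' @export
example_study_edits <- function(study_map) {
  has_protocol <- function(run, pattern) {
    grepl(pattern, run$attributes$ProtocolName %||% "", ignore.case = TRUE)
  }
  study_map <- edit_run_items(
    study_map, TOY_FORMAT,
    where = function(run) run$datatype == "func" && has_protocol(run, "mb8"),
    bids = list(task = "Reward", acq = "mb8"))
  study_map <- edit_run_items(
    study_map, TOY_FORMAT,
    where = function(run) run$datatype == "func" && has_protocol(run, "mb3me3"),
    bids = list(task = "Stop", acq = "mb3me3"))
  study_map <- edit_run_items(
    study_map, TOY_FORMAT,
    where = function(run) run$datatype == "anat" && has_protocol(run, "mprage"),
    bids = list(acq = "mprage"))
  study_map <- edit_run_items(
    study_map, TOY_FORMAT,
    where = function(run) run$datatype == "fmap" && has_protocol(run, "2p4"),
    meta = list(IntendedFor = "<<Reward>>"))
  study_map <- edit_run_items(
    study_map, TOY_FORMAT,
    where = function(run) run$datatype == "fmap" && has_protocol(run, "2p5"),
    meta = list(IntendedFor = "<<Stop>>"))
  set_subject_session(study_map, TOY_FORMAT, session = "")
}
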