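# Conversion ("coining"): turn every source session into BIDS output as
# prescribed by the study bidsmap.
#
# Per session, every sample group is matched against the study map only.
# Ignored datatypes are skipped; for the rest, coining-time dynamic
# values are resolved, the output name composed (with run-index
# auto-increment), the data file and merged JSON sidecar written, and the
# participants table and dataset scaffolding updated. Fieldmaps are coined
# after all other datatypes within a session so that their IntendedFor
# wildcard lookups see the final functional file names. A coining run
# only adds files — it never deletes or truncates pre-existing output —
# and subjects that already have non-empty output are skipped unless
# forced.

#' Resolve a dynamic run index against existing output
#'
#' When the composed name carries a dynamic run seed (`run-<<n>>`), the
#' index starts at the seed and is incremented while an output file with
#' that run index already exists in the target folder.
#'
#' @param target_folder Output datatype folder.
#' @param name Composed BIDS name (no extension), possibly containing a
#'   `run-<<n>>` chunk; returned unchanged when it does not.
#' @return The name with the final run index substituted.
#' @export
#' @examples
#' # with sub-001_run-1_T1w.nii.gz present, a <<1>> seed resolves to run-2
assign_run_index <- function(target_folder, name) {
  m <- regexpr("run-<<([0-9]+)>>", name, perl = TRUE)
  if (m < 0L) return(name)
  cs <- attr(m, "capture.start")[1L]
  cl <- attr(m, "capture.length")[1L]
  idx <- as.integer(substr(name, cs, cs + cl - 1L))
  existing <- if (dir.exists(target_folder)) list.files(target_folder) else character(0)
  repeat {
    candidate <- sub("run-<<[0-9]+>>", paste0("run-", idx), name)
    taken <- any(existing == candidate |
                   startsWith(existing, paste0(candidate, ".")))
    if (!taken) return(candidate)
    idx <- idx + 1L
  }
}

#' Resolve an IntendedFor wildcard expression
#'
#' The sidecar value is a coining-time dynamic expression of one or more
#' `><`-separated shell-style wildcard patterns (e.g. `<<task>>` or
#' `<<Stop*Go><Reward>>`). Each pattern is wrapped as `*pattern*` and
#' glob-matched against the imaging file names already on disk under the
#' subject (or subject/session) folder; the union is returned,
#' deduplicated and sorted, as paths relative to the subject folder.
#'
#' @param value The dynamic IntendedFor value.
#' @param subject_folder The subject's BIDS output folder.
#' @param session_label Session label (`""` for none); restricts the
#'   search to that session subfolder.
#' @return Character vector of relative paths (possibly empty).
#' @export
resolve_intendedfor <- function(value, subject_folder, session_label = "") {
  inner <- sub("^<<", "", sub(">>$", "", as.character(value)))
  patterns <- strsplit(inner, "><", fixed = TRUE)[[1]]
  patterns <- patterns[nzchar(patterns)]
  if (!length(patterns) || !dir.exists(subject_folder)) return(character(0))
  rel <- list.files(subject_folder, recursive = TRUE)
  rel <- rel[grepl("\\.nii(\\.gz)?$", rel)]
  if (nzchar(session_label)) {
    rel <- rel[startsWith(rel, paste0("ses-", session_label, "/"))]
  }
  hits <- character(0)
  for (p in patterns) {
    rx <- utils::glob2rx(paste0("*", p, "*"))
    hits <- c(hits, rel[grepl(rx, basename(rel))])
  }
  sort(unique(gsub("\\\\", "/", hits)), method = "radix")
}

coerce_meta_value <- function(key, value) {
  if (key != "AcquisitionDate" &&
      grepl("^-?[0-9]+(\\.[0-9]+)?$", value)) {
    return(as.numeric(value))
  }
  value
}

# Standard sidecar fields the toy plugin derives from the header: every
# key except the patient-identifying ones (those feed the participants
# table instead).
toy_sidecar_meta <- function(path) {
  header <- read_toy_header(path)
  if (is.null(header)) return(list())
  header <- header[setdiff(names(header),
                           c("PatientName", "PatientComments", "Sex"))]
  out <- list()
  for (k in names(header)) out[[k]] <- coerce_meta_value(k, header[[k]])
  out
}

#' Merge plugin metadata with the run-item's meta dictionary
#'
#' Starts from the plugin-produced standard sidecar fields, resolves the
#' coining-time dynamics of the run-item's `meta` values against the
#' source, and lets those user values append to or overwrite the standard
#' ones. Keys whose value resolves to empty text are omitted. With the
#' anonymization option, the age is rounded down to whole years and the
#' acquisition date is discarded. `IntendedFor` is left for the caller
#' (see [resolve_intendedfor()]).
#'
#' @param plugin_meta Named list of standard sidecar fields.
#' @param run_meta The run-item's `meta` dictionary.
#' @param source A [data_source()] for dynamic-value lookup.
#' @param anon Apply the anonymization rules.
#' @param quiet Suppress console warnings.
#' @return Named list; key order is the merge order (plugin fields first,
#'   new user keys appended).
#' @export
merge_sidecar <- function(plugin_meta, run_meta, source, anon = FALSE,
                          quiet = FALSE) {
  out <- plugin_meta
  for (key in setdiff(names(run_meta), "IntendedFor")) {
    val <- run_meta[[key]]
    if (is.list(val)) val <- bids_value(val)
    resolved <- resolve_value(as.character(val), source, stage = 2L,
                              used_for = "meta", quiet = quiet)
    if (nzchar(resolved)) {
      out[[key]] <- coerce_meta_value(key, resolved)
    } else {
      out[[key]] <- NULL
    }
  }
  if (anon) {
    if (!is.null(out$Age)) {
      out$Age <- floor(suppressWarnings(as.numeric(out$Age)))
    }
    out$AcquisitionDate <- NULL
  }
  out
}

split_bidsignore <- function(entries) {
  out <- unlist(strsplit(as.character(entries %||% character(0)), ";",
                         fixed = TRUE))
  trimws(out[nzchar(trimws(out))])
}

#' Create the modality-agnostic scaffold files
#'
#' Creates, only when absent: `dataset_description.json` (placeholder
#' name, BIDSVersion 1.6.0), a placeholder `README`, `.bidsignore` (one
#' line per configured entry — semicolon-separated entries are split —
#' plus one per BIDS-like unknowntype folder), and the `participants.tsv`
#' header. Existing files are never overwritten; missing `.bidsignore`
#' lines are appended.
#'
#' @param bidsfolder BIDS output folder (created when needed).
#' @param options Engine options (for `bidsignore`/`unknowntypes`).
#' @return Invisibly, the paths of the scaffold files.
#' @export
scaffold_dataset <- function(bidsfolder, options = bidsmap_options(builtin_template())) {
  dir.create(bidsfolder, recursive = TRUE, showWarnings = FALSE)
  dd <- file.path(bidsfolder, "dataset_description.json")
  if (!file.exists(dd)) {
    jsonlite::write_json(
      list(Name = "TODO: name of the dataset",
           BIDSVersion = "1.6.0",
           DatasetType = "raw",
           GeneratedBy = list(list(
             Name = "bidsforge",
             Version = as.character(utils::packageVersion("bidsforge"))))),
      dd, auto_unbox = TRUE, pretty = 2)
  }
  readme <- file.path(bidsfolder, "README")
  if (!file.exists(readme)) {
    writeLines(c("TODO: describe this dataset.",
                 "",
                 "Converted with bidsforge."), readme)
  }
  ignore <- file.path(bidsfolder, ".bidsignore")
  wanted <- unique(c(split_bidsignore(options$bidsignore),
                     paste0(options$unknowntypes %||% character(0), "/")))
  current <- if (file.exists(ignore)) readLines(ignore, warn = FALSE) else character(0)
  missing <- setdiff(wanted, current)
  if (length(missing)) cat(missing, file = ignore, sep = "\n", append = TRUE)
  participants <- file.path(bidsfolder, "participants.tsv")
  if (!file.exists(participants)) {
    writeLines("participant_id\tsex\tage", participants)
  }
  invisible(c(dd, readme, ignore, participants))
}

participants_append <- function(bidsfolder, id, sex = "", age = "") {
  path <- file.path(bidsfolder, "participants.tsv")
  lines <- if (file.exists(path)) readLines(path, warn = FALSE) else
    "participant_id\tsex\tage"
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
  if (id %in% ids[-1]) return(invisible(FALSE))
  row <- paste(c(id,
                 if (nzchar(sex)) sex else "n/a",
                 if (nzchar(as.character(age))) as.character(age) else "n/a"),
               collapse = "\t")
  writeLines(c(lines, row), path)
  invisible(TRUE)
}

datatype_extension <- function(datatype) {
  spec <- bids_schema()$datatypes[[datatype]]
  if (!is.null(spec$extension)) spec$extension else ".nii.gz"
}

toy_payload <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sep <- match("---", lines)
  if (is.na(sep) || sep == length(lines)) return(character(0))
  lines[(sep + 1L):length(lines)]
}

# Convert one session (the toy plugin's coiner hook). Returns a tibble of
# written imaging files: datatype, path.
coin_session <- function(session, study_map, bidsfolder, quiet = FALSE) {
  opts <- bidsmap_options(study_map)
  anon <- tolower(as.character(
    bidsmap_plugins(study_map)$toyscan$anon %||% "n")) %in% c("y", "yes", "true")
  samples <- collect_samples(session$scan_folder,
                             subject_folder = session$subject_folder,
                             plugins = session$plugins)
  if (!length(samples)) return(NULL)
  matches <- lapply(samples, function(src) find_run_match(src, study_map))
  # fieldmaps last, so IntendedFor globs see the final names of everything else
  dts <- vapply(matches, `[[`, character(1), "datatype")
  ord <- order(dts == "fmap", seq_along(samples))
  subject <- session$subject_label
  ses <- session$session_label
  subject_out <- file.path(bidsfolder, paste0("sub-", subject))
  rows <- list()
  for (i in ord) {
    src <- samples[[i]]
    m <- matches[[i]]
    if (!m$matched) {
      bf_warn(sprintf("no study mapping for %s; storing under extra_data",
                      src$path), quiet = quiet)
    }
    if (m$datatype %in% (opts$ignoretypes %||% character(0))) next
    written <- tryCatch({
      bids_resolved <- resolve_mapping(m$run$bids, src, stage = 2L,
                                       used_for = "bids", quiet = quiet)
      name <- compose_bidsname(subject, ses, m$datatype, bids_resolved)
      outdir <- file.path(bidsfolder,
                          bids_relative_folder(subject, ses, m$datatype))
      name <- assign_run_index(outdir, name)
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      datafile <- file.path(outdir, paste0(name, datatype_extension(m$datatype)))
      writeLines(toy_payload(src$path), datafile)
      meta <- merge_sidecar(toy_sidecar_meta(src$path), m$run$meta, src,
                            anon = anon, quiet = quiet)
      if ("IntendedFor" %in% names(m$run$meta)) {
        intended <- resolve_intendedfor(m$run$meta$IntendedFor, subject_out, ses)
        if (length(intended)) {
          meta$IntendedFor <- intended
        } else {
          bf_warn(sprintf("IntendedFor pattern '%s' matched no files for %s",
                          m$run$meta$IntendedFor, name), quiet = quiet)
        }
      }
      jsonlite::write_json(meta, file.path(outdir, paste0(name, ".json")),
                           auto_unbox = TRUE, pretty = 2, digits = NA)
      bf_info(sprintf("wrote %s", datafile), quiet = quiet)
      tibble::tibble(datatype = m$datatype, path = datafile)
    }, error = function(e) {
      bf_log("ERROR", sprintf("failed to convert %s: %s", src$path,
                              conditionMessage(e)), quiet = quiet)
      NULL
    })
    if (!is.null(written)) rows[[length(rows) + 1L]] <- written
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Convert a raw tree to BIDS per the study bidsmap
#'
#' Requires a green study bidsmap at its conventional location inside
#' `bidsfolder` (created by [run_bidsmapper()], refined with
#' [edit_run_items()]); conversion refuses to start while any non-ignored
#' run-item still has validation issues. Subjects whose output folder
#' already exists and is non-empty are skipped, unless `force` is set or
#' they are explicitly listed in `participants` (which also restricts the
#' run to those subjects). Per-file failures are recorded and conversion
#' continues.
#'
#' @param rawfolder Source data root.
#' @param bidsfolder BIDS output folder.
#' @param participants Optional subject list (raw folder names or
#'   `sub-<label>` output names) to (re)process.
#' @param force Reprocess subjects with existing output.
#' @param quiet Suppress console output.
#' @return A `conversion_report`: per-subject status
#'   (processed/skipped/failed), files written per datatype, and the run's
#'   warnings and errors.
#' @export
run_bidscoiner <- function(rawfolder, bidsfolder, participants = NULL,
                           force = FALSE, quiet = FALSE) {
  bf_log_reset()
  study_path <- study_bidsmap_path(bidsfolder)
  if (!file.exists(study_path)) {
    stop(sprintf(
      "study bidsmap not found at %s; run the bidsmapper stage first",
      study_path), call. = FALSE)
  }
  study_map <- load_bidsmap(study_path, quiet = quiet)
  opts <- bidsmap_options(study_map)
  plugins <- names(bidsmap_plugins(study_map))
  report <- validate_bidsmap(study_map)
  red <- report[!report$valid, , drop = FALSE]
  if (nrow(red)) {
    items <- vapply(seq_len(nrow(red)), function(i) {
      sprintf("%s/%s run %d: %s", red$format[i], red$datatype[i], red$index[i],
              paste(red$issues[[i]], collapse = "; "))
    }, character(1))
    stop(paste0("study bidsmap has invalid (red) run-items:\n  ",
                paste(items, collapse = "\n  ")), call. = FALSE)
  }
  scaffold_dataset(bidsfolder, opts)
  sessions <- discover_sessions(rawfolder, opts$subprefix %||% "sub-",
                                opts$sesprefix %||% "ses-", quiet = quiet)
  subjects <- unique(sessions$subject_folder)
  subj_rows <- list()
  file_rows <- list()
  for (subj in subjects) {
    subj_sessions <- sessions[sessions$subject_folder == subj, , drop = FALSE]
    status <- "processed"
    n_files <- 0L
    # labels come from the section's subject/session extractors, resolved
    # against the first sample of the first session
    first_scan <- if (nzchar(subj_sessions$session_folder[1])) {
      subj_sessions$session_folder[1]
    } else {
      subj
    }
    samples <- collect_samples(first_scan, subject_folder = subj,
                               plugins = plugins)
    if (!length(samples)) {
      bf_warn(sprintf("no supported source files for %s; skipped", subj),
              quiet = quiet)
      subj_rows[[length(subj_rows) + 1L]] <- tibble::tibble(
        subject = basename(subj), status = "skipped", n_files = 0L)
      next
    }
    section <- bidsmap_section(study_map, samples[[1]]$format_name)
    label <- resolve_value(section$subject, samples[[1]], stage = 2L,
                           used_for = "subject", quiet = quiet)
    if (!nzchar(label)) {
      label <- sanitize_label(sub(paste0("^", opts$subprefix %||% ""), "",
                                  basename(subj)))
    }
    id <- paste0("sub-", label)
    selected <- is.null(participants) ||
      basename(subj) %in% participants || id %in% participants
    if (!selected) {
      subj_rows[[length(subj_rows) + 1L]] <- tibble::tibble(
        subject = basename(subj), status = "skipped", n_files = 0L)
      next
    }
    out_sub <- file.path(bidsfolder, id)
    has_output <- dir.exists(out_sub) && length(list.files(out_sub)) > 0L
    forced <- force || (!is.null(participants) &&
                          (basename(subj) %in% participants || id %in% participants))
    if (has_output && !forced) {
      bf_info(sprintf("%s already has output; skipped (use force to redo)", id),
              quiet = quiet)
      subj_rows[[length(subj_rows) + 1L]] <- tibble::tibble(
        subject = basename(subj), status = "skipped", n_files = 0L)
      next
    }
    for (i in seq_len(nrow(subj_sessions))) {
      sesdir <- subj_sessions$session_folder[i]
      ses_label <- ""
      scan_folder <- if (nzchar(sesdir)) sesdir else subj
      ses_samples <- if (i == 1L) samples else
        collect_samples(scan_folder, subject_folder = subj, plugins = plugins)
      if (!length(ses_samples)) next
      ses_label <- resolve_value(section$session, ses_samples[[1]], stage = 2L,
                                 used_for = "subject", quiet = quiet)
      session <- list(scan_folder = scan_folder, subject_folder = subj,
                      plugins = plugins, subject_label = label,
                      session_label = ses_label)
      for (pname in plugins) {
        plugin <- get_plugin(pname)
        if (is.null(plugin)) next
        res <- tryCatch(
          plugin$bidscoiner_plugin(session, study_map, bidsfolder,
                                   quiet = quiet),
          error = function(e) {
            bf_log("ERROR", sprintf("plugin '%s' failed on %s: %s", pname,
                                    scan_folder, conditionMessage(e)),
                   quiet = quiet)
            status <<- "failed"
            NULL
          })
        if (!is.null(res) && nrow(res)) {
          n_files <- n_files + nrow(res)
          file_rows[[length(file_rows) + 1L]] <-
            tibble::tibble(subject = id, res)
        }
      }
    }
    sex <- get_attribute(samples[[1]]$format_name, samples[[1]]$path, "Sex")
    age <- get_attribute(samples[[1]]$format_name, samples[[1]]$path, "Age")
    anon <- tolower(as.character(
      bidsmap_plugins(study_map)$toyscan$anon %||% "n")) %in% c("y", "yes", "true")
    if (anon && nzchar(age)) {
      age <- as.character(floor(suppressWarnings(as.numeric(age))))
    }
    participants_append(bidsfolder, id, sex, age)
    subj_rows[[length(subj_rows) + 1L]] <- tibble::tibble(
      subject = basename(subj), status = status, n_files = n_files)
  }
  subjects_tbl <- if (length(subj_rows)) do.call(rbind, subj_rows) else
    tibble::tibble(subject = character(0), status = character(0),
                   n_files = integer(0))
  files_tbl <- if (length(file_rows)) do.call(rbind, file_rows) else
    tibble::tibble(subject = character(0), datatype = character(0),
                   path = character(0))
  write_logs(bidsfolder, tool = "bidscoiner")
  structure(list(subjects = subjects_tbl, files = files_tbl,
                 events = bf_log_events()),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  counts <- table(factor(x$subjects$status,
                         levels = c("processed", "skipped", "failed")))
  cat(sprintf("<conversion_report> %d subject(s): %d processed, %d skipped, %d failed; %d file(s) written\n",
              nrow(x$subjects), counts[["processed"]], counts[["skipped"]],
              counts[["failed"]], nrow(x$files)))
  nw <- sum(vapply(x$events, function(e) e$level != "INFO", logical(1)))
  if (nw) cat(sprintf("  %d warning(s)/error(s) — see code/bidscoin/bidscoiner.errors\n", nw))
  invisible(x)
}
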