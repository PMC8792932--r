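# Data discovery: scan a raw tree and build (or refresh) the study bidsmap.
#
# Every representative sample of every session is matched first against
# the EXISTING study map — a study match means the data type is already
# known and any user edits to it survive — and only then against the
# template. A template match is narrowed (attribute patterns replaced by
# the literal header values, mapping-time dynamics resolved) and appended
# to the study map unless an equivalent run-item is already present. A
# sample matching nothing is stored under extra_data with a synthesized
# catch-all rule.

# Map one session's samples into the study map (the toy plugin's mapper
# hook). Returns the updated study map.
map_session_samples <- function(session, study_map, template_map, quiet = FALSE) {
  samples <- collect_samples(session$scan_folder,
                             subject_folder = session$subject_folder,
                             plugins = session$plugins)
  for (src in samples) {
    known <- find_run_match(src, study_map)
    if (known$matched) next
    tpl <- find_run_match(src, template_map)
    run <- expand_template_run(tpl$run, src)
    run$datatype <- tpl$datatype
    run$format_name <- src$format_name
    res <- insert_run(study_map, run)
    study_map <- res$bidsmap
    if (res$inserted) {
      bf_info(sprintf("discovered %s/%s data type: %s",
                      src$format_name, tpl$datatype, src$path), quiet = quiet)
    }
  }
  study_map
}

# Skeleton study map: template options, and per data-format section the
# subject/session extractors plus empty run lists in template datatype
# order (so learned run-items land in canonical precedence order).
study_skeleton <- function(template) {
  study <- list(Options = template$Options)
  for (fmt in bidsmap_formats(template)) {
    sec <- template[[fmt]]
    skel <- list(subject = sec$subject %||% "", session = sec$session %||% "")
    for (dt in setdiff(names(sec), c("subject", "session"))) {
      skel[[dt]] <- list()
    }
    study[[fmt]] <- skel
  }
  structure(study, class = "bidsmap")
}

#' Scan a raw tree and produce or refresh the study bidsmap
#'
#' For every subject\[/session\] and every representative sample, matches
#' the study map first, then the template; unmatched-by-study samples are
#' narrowed from their template rule and inserted. A pre-existing study
#' map at `<bidsfolder>/code/bidscoin/bidsmap.yaml` is reloaded first, so
#' prior edits survive and re-running after new acquisitions only appends
#' the new data types. The result is saved back to that location.
#'
#' @param rawfolder Source data root (subject\[/session\] organization).
#' @param bidsfolder BIDS output folder (hosts the study map).
#' @param template Template bidsmap (default: [builtin_template()]).
#' @param quiet Suppress console output.
#' @return The study `bidsmap`, invisibly.
#' @export
run_bidsmapper <- function(rawfolder, bidsfolder, template = builtin_template(),
                           quiet = FALSE) {
  bf_log_reset()
  opts <- bidsmap_options(template)
  plugins <- names(bidsmap_plugins(template))
  study_path <- study_bidsmap_path(bidsfolder)
  study_map <- if (file.exists(study_path)) {
    bf_info(sprintf("reloading existing study bidsmap: %s", study_path),
            quiet = quiet)
    load_bidsmap(study_path, quiet = quiet)
  } else {
    study_skeleton(template)
  }
  sessions <- discover_sessions(rawfolder, opts$subprefix %||% "sub-",
                                opts$sesprefix %||% "ses-", quiet = quiet)
  if (!nrow(sessions)) {
    bf_warn(sprintf("no source data found under %s", rawfolder), quiet = quiet)
  }
  for (i in seq_len(nrow(sessions))) {
    scan_folder <- if (nzchar(sessions$session_folder[i])) {
      sessions$session_folder[i]
    } else {
      sessions$subject_folder[i]
    }
    session <- list(scan_folder = scan_folder,
                    subject_folder = sessions$subject_folder[i],
                    plugins = plugins)
    for (pname in plugins) {
      plugin <- get_plugin(pname)
      if (is.null(plugin)) {
        bf_warn(sprintf("plugin '%s' listed in Options is not registered", pname),
                quiet = quiet)
        next
      }
      study_map <- plugin$bidsmapper_plugin(session, study_map, template,
                                            quiet = quiet)
    }
  }
  save_bidsmap(study_map, study_path)
  n_runs <- length(bidsmap_runs(study_map))
  bf_info(sprintf("study bidsmap with %d run-item(s) saved to %s",
                  n_runs, study_path), quiet = quiet)
  write_logs(bidsfolder, tool = "bidsmapper")
  invisible(study_map)
}
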