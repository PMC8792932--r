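# Event logging shared by all conversion stages.
#
# Every routine reports through bf_log(), which prints to the console and
# records the event in a session-level buffer. write_logs() flushes the
# buffer to <bids>/code/bidscoin/<tool>.log (all events) and <tool>.errors
# (warnings and errors only), append mode with timestamps, so consecutive
# runs accumulate a full provenance trail next to the output data.

.bf_state <- new.env(parent = emptyenv())

bf_log_reset <- function() {
  .bf_state$events <- list()
  invisible(NULL)
}

#' Log an event
#'
#' Prints a level-prefixed message to the console and records it so that a
#' later [write_logs()] call can mirror the full console output into the
#' dataset's log files.
#'
#' @param level One of `"INFO"`, `"WARNING"`, `"ERROR"`.
#' @param msg Message text.
#' @param quiet Suppress console output (the event is still recorded).
#' @return The event, invisibly.
#' @keywords internal
bf_log <- function(level = c("INFO", "WARNING", "ERROR"), msg, quiet = FALSE) {
  level <- match.arg(level)
  if (is.null(.bf_state$events)) .bf_state$events <- list()
  event <- list(time = Sys.time(), level = level, msg = msg)
  .bf_state$events[[length(.bf_state$events) + 1L]] <- event
  if (!quiet) message(sprintf("%s | %s", level, msg))
  invisible(event)
}

bf_warn <- function(msg, quiet = FALSE) bf_log("WARNING", msg, quiet = quiet)
bf_info <- function(msg, quiet = FALSE) bf_log("INFO", msg, quiet = quiet)

#' Retrieve the events logged since the last reset
#' @return A list of events (time, level, msg).
#' @keywords internal
bf_log_events <- function() {
  if (is.null(.bf_state$events)) list() else .bf_state$events
}

#' Write accumulated log events into the dataset
#'
#' Creates `<bidsfolder>/code/bidscoin/<tool>.log` with every event and
#' `<tool>.errors` with warnings and errors only. Both files are appended
#' to, never truncated, so earlier runs remain inspectable.
#'
#' @param bidsfolder BIDS output folder.
#' @param events List of events as produced by [bf_log_events()].
#' @param tool Base name for the log files (default `"bidscoiner"`).
#' @return Invisibly, the path of the `.log` file.
#' @export
write_logs <- function(bidsfolder, events = bf_log_events(), tool = "bidscoiner") {
  logdir <- file.path(bidsfolder, "code", "bidscoin")
  dir.create(logdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(logdir, paste0(tool, ".log"))
  errfile <- file.path(logdir, paste0(tool, ".errors"))
  fmt <- function(e) {
    sprintf("%s %s %s", format(e$time, "%Y-%m-%d %H:%M:%S"), e$level, e$msg)
  }
  lines <- vapply(events, fmt, character(1))
  err <- vapply(events, function(e) e$level %in% c("WARNING", "ERROR"), logical(1))
  # touch both files even when there is nothing to say: a clean run leaves
  # an (empty) .errors file behind as evidence that it was checked
  if (!file.exists(errfile)) file.create(errfile)
  if (length(lines)) cat(lines, file = logfile, sep = "\n", append = TRUE)
  if (any(err)) cat(lines[err], file = errfile, sep = "\n", append = TRUE)
  invisible(logfile)
}
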