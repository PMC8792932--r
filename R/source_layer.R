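# The source-data layer.
#
# All interaction with source files goes through a plugin with five
# functions, so new source formats can be added without touching the
# engine:
#
#   test(options)                         -> list(ok, message)
#   is_sourcefile(path)                   -> format name or ""
#   get_attribute(format, path, key, opts)-> character ("" when unknown)
#   bidsmapper_plugin(session, study, template, ...) -> study map
#   bidscoiner_plugin(session, study, bidsfolder, ...) -> report rows
#
# The built-in "toyscan" plugin reads a plain-text scan format used by the
# synthetic data generator: line 1 is the magic marker "TOYSCAN/1",
# followed by "Key: value" header lines, a "---" separator, and arbitrary
# payload bytes. Header keys mirror the DICOM attributes the engine cares
# about (ProtocolName, SeriesNumber, EchoNumber, PatientName, ...).

TOY_MAGIC <- "TOYSCAN/1"
TOY_FORMAT <- "Toy"

.bf_plugins <- new.env(parent = emptyenv())

#' Register a plugin
#'
#' A plugin is a named list providing the five-function contract. Only
#' plugins listed in the bidsmap Options are consulted by the engine.
#'
#' @param name Plugin name (the Options key).
#' @param plugin Named list of functions: `test`, `is_sourcefile`,
#'   `get_attribute`, `bidsmapper_plugin`, `bidscoiner_plugin`.
#' @return `name`, invisibly.
#' @export
register_plugin <- function(name, plugin) {
  assign(name, plugin, envir = .bf_plugins)
  invisible(name)
}

#' Look up a registered plugin by name
#' @param name Plugin name.
#' @return The plugin list, or `NULL` when unknown.
#' @export
get_plugin <- function(name) {
  if (exists(name, envir = .bf_plugins, inherits = FALSE)) {
    get(name, envir = .bf_plugins, inherits = FALSE)
  } else {
    NULL
  }
}

plugin_contract_functions <- function() {
  c("test", "is_sourcefile", "get_attribute",
    "bidsmapper_plugin", "bidscoiner_plugin")
}

#' Audit a plugin and its options
#'
#' Checks that the plugin provides the whole five-function contract, then
#' delegates to the plugin's own `test()`. For a plugin whose options name
#' an external `command`, the test checks that the command resolves on the
#' system path.
#'
#' @param plugin Plugin list or registered plugin name.
#' @param options Plugin option list (e.g. from the bidsmap Options block).
#' @return A list with `ok` (logical) and `message`.
#' @export
test_plugin <- function(plugin, options = list()) {
  if (is.character(plugin)) {
    name <- plugin
    plugin <- get_plugin(plugin)
    if (is.null(plugin)) {
      return(list(ok = FALSE, message = sprintf("plugin '%s' is not registered", name)))
    }
  }
  missing <- setdiff(plugin_contract_functions(), names(plugin))
  if (length(missing)) {
    return(list(ok = FALSE,
                message = sprintf("plugin is missing contract function(s): %s",
                                  paste(missing, collapse = ", "))))
  }
  plugin$test(options)
}

# ---- toy scan format ------------------------------------------------------

read_toy_header <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE, encoding = "UTF-8"),
                    error = function(e) character(0))
  if (!length(lines) || lines[1L] != TOY_MAGIC) return(NULL)
  header <- list()
  for (ln in lines[-1L]) {
    if (ln == "---") break
    colon <- regexpr(": ", ln, fixed = TRUE)
    if (colon < 0L) {
      bf_warn(sprintf("malformed header line in %s: '%s'", path, ln))
      next
    }
    key <- substr(ln, 1L, colon - 1L)
    header[[key]] <- substr(ln, colon + 2L, nchar(ln))
  }
  header
}

#' Decide whether a file is a supported source file
#'
#' Consults the registered plugins (the built-in toy-scan reader by
#' default) and returns the data-format name the file belongs to — the
#' name of the matching data-format section in a bidsmap — or `""`.
#' Unreadable files are never fatal: they yield `""` with a warning so
#' that discovery over a large archive keeps going.
#'
#' @param path File path.
#' @param plugins Character vector of plugin names to consult.
#' @return Format name (e.g. `"Toy"`) or `""`.
#' @export
is_sourcefile <- function(path, plugins = "toyscan") {
  if (!file.exists(path) || dir.exists(path)) return("")
  for (pname in plugins) {
    plugin <- get_plugin(pname)
    if (is.null(plugin)) next
    fmt <- plugin$is_sourcefile(path)
    if (nzchar(fmt)) return(fmt)
  }
  ""
}

#' Read one header attribute from a source file
#'
#' Dispatches to the plugin owning `format`. Unknown keys and malformed
#' headers yield `""` (with a warning for the latter), never an error.
#'
#' @param format Data-format name as returned by [is_sourcefile()].
#' @param path Source file path.
#' @param key Attribute name, e.g. `"ProtocolName"`.
#' @param plugins Plugin names to consult.
#' @return Attribute value as text, `""` when absent.
#' @export
get_attribute <- function(format, path, key, plugins = "toyscan") {
  for (pname in plugins) {
    plugin <- get_plugin(pname)
    if (is.null(plugin)) next
    val <- plugin$get_attribute(format, path, key)
    if (!is.null(val)) return(val)
  }
  ""
}

toy_plugin <- function() {
  list(
    test = function(options = list()) {
      if (!identical(TOY_MAGIC, "TOYSCAN/1")) {
        return(list(ok = FALSE, message = "toy magic marker corrupted"))
      }
      cmd <- options[["command"]]
      if (!is.null(cmd) && nzchar(cmd) && Sys.which(cmd) == "") {
        return(list(ok = FALSE,
                    message = sprintf("command '%s' not found on PATH", cmd)))
      }
      list(ok = TRUE, message = "toy plugin operational")
    },
    is_sourcefile = function(path) {
      first <- tryCatch(readLines(path, n = 1L, warn = FALSE),
                        error = function(e) character(0))
      if (!length(first)) {
        bf_warn(sprintf("unreadable or empty file skipped: %s", path))
        return("")
      }
      if (identical(first, TOY_MAGIC)) TOY_FORMAT else ""
    },
    get_attribute = function(format, path, key) {
      if (!identical(format, TOY_FORMAT)) return(NULL)
      header <- read_toy_header(path)
      if (is.null(header)) {
        bf_warn(sprintf("malformed toy header in %s", path))
        return("")
      }
      val <- header[[key]]
      if (is.null(val)) "" else val
    },
    bidsmapper_plugin = function(session, study_map, template_map, quiet = FALSE) {
      map_session_samples(session, study_map, template_map, quiet = quiet)
    },
    bidscoiner_plugin = function(session, study_map, bidsfolder, quiet = FALSE) {
      coin_session(session, study_map, bidsfolder, quiet = quiet)
    }
  )
}

# An external-command plugin shell: models converters that wrap a binary.
# Its test() checks that the configured command resolves; the engine never
# needs the binary itself.
command_plugin <- function(format_name = "External") {
  list(
    test = function(options = list()) {
      cmd <- options[["command"]]
      if (is.null(cmd) || !nzchar(cmd)) {
        return(list(ok = FALSE, message = "no command configured"))
      }
      if (Sys.which(cmd) == "") {
        return(list(ok = FALSE,
                    message = sprintf("command '%s' not found on PATH", cmd)))
      }
      list(ok = TRUE, message = sprintf("command '%s' resolves", cmd))
    },
    is_sourcefile = function(path) "",
    get_attribute = function(format, path, key) NULL,
    bidsmapper_plugin = function(session, study_map, template_map, quiet = FALSE) study_map,
    bidscoiner_plugin = function(session, study_map, bidsfolder, quiet = FALSE) NULL
  )
}

.onLoad <- function(libname, pkgname) {
  register_plugin("toyscan", toy_plugin())
  register_plugin("external", command_plugin())
  bf_log_reset()
}

# ---- data sources ---------------------------------------------------------

#' Construct a data source
#'
#' A data source is one representative source file plus its data-format
#' name and grouping key; it is the engine's gateway to file properties
#' and header attributes.
#'
#' @param path Source file path (must exist).
#' @param format_name Data-format name; inferred via [is_sourcefile()]
#'   when omitted.
#' @param subject_folder,session_folder Folders the file was discovered
#'   under (default: inferred as the parent folders).
#' @return An object of class `data_source`.
#' @export
data_source <- function(path, format_name = NULL,
                        subject_folder = NULL, session_folder = NULL) {
  stopifnot(file.exists(path))
  if (is.null(format_name)) format_name <- is_sourcefile(path)
  if (!nzchar(format_name)) {
    stop(sprintf("'%s' is not a supported source file", path), call. = FALSE)
  }
  series <- get_attribute(format_name, path, "SeriesNumber")
  echo <- get_attribute(format_name, path, "EchoNumber")
  structure(
    list(
      path = posix_path(path),
      format_name = format_name,
      group_key = c(series = series, echo = echo),
      session_folder = posix_path(session_folder %||% dirname(dirname(path))),
      subject_folder = posix_path(subject_folder %||% dirname(dirname(path)))
    ),
    class = "data_source"
  )
}

#' @export
print.data_source <- function(x, ...) {
  cat(sprintf("<data_source[%s]> %s (series %s%s)\n",
              x$format_name, x$path, x$group_key[["series"]],
              if (nzchar(x$group_key[["echo"]])) paste0(", echo ", x$group_key[["echo"]]) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

posix_path <- function(path) {
  if (is.null(path)) return("")
  gsub("\\\\", "/", path)
}

# ---- discovery ------------------------------------------------------------

#' Discover subject/session folders in a raw tree
#'
#' One row per `sesprefix` subfolder of each `subprefix` subfolder;
#' subjects without session subfolders yield a single row with an empty
#' session. Order is deterministic (lexicographic).
#'
#' @param rawfolder Root of the source data tree.
#' @param subprefix Subject folder prefix (e.g. `"sub-"`; `""` matches all).
#' @param sesprefix Session folder prefix (e.g. `"ses-"`).
#' @param quiet Suppress console warnings.
#' @return A tibble with columns `subject_folder`, `session_folder` (`""`
#'   when the subject has no session level).
#' @export
discover_sessions <- function(rawfolder, subprefix = "sub-", sesprefix = "ses-",
                              quiet = FALSE) {
  empty <- tibble::tibble(subject_folder = character(0),
                          session_folder = character(0))
  if (!dir.exists(rawfolder)) {
    bf_warn(sprintf("raw folder not found: %s", rawfolder), quiet = quiet)
    return(empty)
  }
  subs <- list.dirs(rawfolder, recursive = FALSE, full.names = TRUE)
  subs <- subs[startsWith(basename(subs), subprefix)]
  subs <- sort(subs, method = "radix")
  if (!length(subs)) {
    bf_warn(sprintf("no '%s*' subject folders found in %s", subprefix, rawfolder),
            quiet = quiet)
    return(empty)
  }
  rows <- lapply(subs, function(s) {
    sess <- list.dirs(s, recursive = FALSE, full.names = TRUE)
    sess <- sess[nzchar(sesprefix) & startsWith(basename(sess), sesprefix)]
    sess <- sort(sess, method = "radix")
    if (length(sess)) {
      tibble::tibble(subject_folder = posix_path(s),
                     session_folder = posix_path(sess))
    } else {
      tibble::tibble(subject_folder = posix_path(s), session_folder = "")
    }
  })
  do.call(rbind, rows)
}

#' Collect representative samples from a session
#'
#' Recursively finds supported source files, groups them by
#' `(SeriesNumber, EchoNumber-or-empty)` and returns the lexicographically
#' first file of each group as that group's representative. A multi-echo
#' series therefore contributes one sample per echo, matching converters
#' that split such series into per-echo outputs. Results are ordered by
#' group key (numeric series, then echo).
#'
#' @param session_folder Folder of one subject\[/session\].
#' @param subject_folder Owning subject folder (defaults to
#'   `session_folder`).
#' @param plugins Plugin names to consult.
#' @return List of [data_source()] objects (empty when nothing is
#'   supported).
#' @export
collect_samples <- function(session_folder, subject_folder = session_folder,
                            plugins = "toyscan") {
  files <- sort(list.files(session_folder, recursive = TRUE, full.names = TRUE),
                method = "radix")
  files <- files[!dir.exists(files)]
  if (!length(files)) return(list())
  fmts <- vapply(files, is_sourcefile, character(1), plugins = plugins,
                 USE.NAMES = FALSE)
  keep <- nzchar(fmts)
  files <- files[keep]
  fmts <- fmts[keep]
  if (!length(files)) return(list())
  series <- vapply(seq_along(files), function(i) {
    get_attribute(fmts[i], files[i], "SeriesNumber", plugins = plugins)
  }, character(1))
  echo <- vapply(seq_along(files), function(i) {
    get_attribute(fmts[i], files[i], "EchoNumber", plugins = plugins)
  }, character(1))
  key <- paste(series, echo, sep = "\r")
  reps <- tapply(seq_along(files), key, function(idx) idx[1L])
  idx <- unname(reps)
  num_series <- suppressWarnings(as.numeric(series[idx]))
  num_echo <- suppressWarnings(as.numeric(echo[idx]))
  num_echo[is.na(num_echo)] <- -1
  ord <- order(num_series, num_echo, files[idx], method = "radix")
  idx <- idx[ord]
  lapply(idx, function(i) {
    data_source(files[i], fmts[i],
                subject_folder = subject_folder,
                session_folder = session_folder)
  })
}

#' Tabulate header values across a raw tree
#'
#' One row per sample per session with the requested attribute values —
#' handy for a first inspection of what was acquired (echo times, subject
#' sex, acquisition dates, ...). Unknown keys yield empty cells.
#'
#' @param rawfolder Root of the source data tree.
#' @param keys Non-empty character vector of attribute names.
#' @param subprefix,sesprefix Folder prefixes, as in [discover_sessions()].
#' @return A tibble: `subject`, `session`, `series`, then one column per
#'   key.
#' @export
inspect_values <- function(rawfolder, keys, subprefix = "sub-", sesprefix = "ses-") {
  stopifnot(length(keys) >= 1L)
  sessions <- discover_sessions(rawfolder, subprefix, sesprefix, quiet = TRUE)
  rows <- list()
  for (i in seq_len(nrow(sessions))) {
    sesdir <- sessions$session_folder[i]
    subdir <- sessions$subject_folder[i]
    scan_dir <- if (nzchar(sesdir)) sesdir else subdir
    samples <- collect_samples(scan_dir, subject_folder = subdir)
    for (src in samples) {
      vals <- vapply(keys, function(k) {
        get_attribute(src$format_name, src$path, k)
      }, character(1))
      row <- c(
        list(subject = basename(subdir),
             session = if (nzchar(sesdir)) basename(sesdir) else "",
             series = basename(dirname(src$path))),
        as.list(vals)
      )
      rows[[length(rows) + 1L]] <- tibble::as_tibble(row)
    }
  }
  if (!length(rows)) {
    cols <- c(list(subject = character(0), session = character(0),
                   series = character(0)),
              stats::setNames(rep(list(character(0)), length(keys)), keys))
    return(tibble::as_tibble(cols))
  }
  do.call(rbind, rows)
}
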