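# The matching engine.
#
# A run-item matches a source file when every non-empty pattern in its
# "properties" and "attributes" input dictionaries matches the
# corresponding extracted value. Patterns are regular expressions with
# FULL-match semantics (the pattern must cover the entire value), so that
# a study run-item whose patterns are narrowed to literal header text acts
# as an exact matcher. Within a data-format section, run-items are tried
# in strict document order across datatypes; the first match wins, and
# datatype order in a template (exclude first, extra_data last) therefore
# defines precedence.

#' The four file-property keys
#' @return `c("filepath", "filename", "filesize", "nrfiles")`.
#' @export
property_keys <- function() c("filepath", "filename", "filesize", "nrfiles")

#' Extract a file-system property from a source
#'
#' @param source A [data_source()].
#' @param key One of [property_keys()]: `filepath` (full POSIX-style
#'   path), `filename` (last component), `filesize` (bytes, decimal text),
#'   `nrfiles` (number of files in the containing folder, decimal text).
#' @return Character scalar.
#' @export
extract_property <- function(source, key) {
  if (!key %in% property_keys()) {
    stop(sprintf("unknown property key '%s'; allowed keys: %s",
                 key, paste(property_keys(), collapse = ", ")), call. = FALSE)
  }
  switch(key,
    filepath = posix_path(source$path),
    filename = basename(source$path),
    filesize = format(file.size(source$path), scientific = FALSE, trim = TRUE),
    nrfiles = {
      sibs <- list.files(dirname(source$path), full.names = TRUE)
      format(sum(!dir.exists(sibs)), scientific = FALSE, trim = TRUE)
    }
  )
}

#' Match a value against a rule pattern
#'
#' An empty or absent pattern always matches. A non-empty pattern is a
#' regular expression that must match the ENTIRE value.
#'
#' @param pattern Regular expression (or `""`/`NULL`).
#' @param value Value to test (converted to text).
#' @return Logical scalar.
#' @export
#' @examples
#' match_value(".*(mprage|T1w).*", "t1_mprage_sag_p2_iso_1.0")  # TRUE
#' match_value("T1w", "T1w_extra")                              # FALSE
match_value <- function(pattern, value) {
  if (is.null(pattern) || length(pattern) == 0L) return(TRUE)
  pattern <- as.character(pattern)
  if (is.na(pattern) || !nzchar(pattern)) return(TRUE)
  value <- as.character(value)
  anchored <- paste0("^(?:", pattern, ")$")
  ok <- tryCatch(suppressWarnings(grepl(anchored, value, perl = TRUE)),
                 error = function(e) {
                   stop(sprintf("invalid regular expression pattern '%s': %s",
                                pattern, conditionMessage(e)), call. = FALSE)
                 })
  isTRUE(ok)
}

#' Test a source against one run-item's input filters
#'
#' True iff every non-empty properties pattern matches its extracted file
#' property AND every non-empty attributes pattern matches the source
#' header attribute. An absent source attribute (empty text) against a
#' non-empty pattern fails.
#'
#' @param source A [data_source()].
#' @param run A run-item (list with `properties` and `attributes`).
#' @return Logical scalar.
#' @export
match_run <- function(source, run) {
  props <- run$properties %||% list()
  for (key in names(props)) {
    pat <- props[[key]]
    if (is.null(pat) || !nzchar(as.character(pat))) next
    if (!match_value(pat, extract_property(source, key))) return(FALSE)
  }
  attrs <- run$attributes %||% list()
  for (key in names(attrs)) {
    pat <- attrs[[key]]
    if (is.null(pat) || !nzchar(as.character(pat))) next
    val <- get_attribute(source$format_name, source$path, key)
    if (!match_value(pat, val)) return(FALSE)
  }
  TRUE
}

#' Find the first run-item matching a source
#'
#' Scans the run-items of the source's data-format section in strict
#' document order across datatypes and returns the first match. When
#' nothing matches, a catch-all run-item with all-empty patterns is
#' synthesized under the `extra_data` datatype.
#'
#' @param source A [data_source()].
#' @param bidsmap A bidsmap.
#' @return A list: `matched` (did an existing run-item match), `datatype`,
#'   `run` (the run-item, enriched with `datatype` and `format_name`), and
#'   `index` (position within its datatype list, `NA` for the synthesized
#'   catch-all).
#' @export
find_run_match <- function(source, bidsmap) {
  section <- bidsmap_section(bidsmap, source$format_name)
  if (is.null(section)) {
    stop(sprintf("bidsmap has no section for data format '%s'",
                 source$format_name), call. = FALSE)
  }
  for (datatype in names(section$runs)) {
    runs <- section$runs[[datatype]]
    for (i in seq_along(runs)) {
      if (match_run(source, runs[[i]])) {
        run <- runs[[i]]
        run$datatype <- datatype
        run$format_name <- source$format_name
        return(list(matched = TRUE, datatype = datatype, run = run, index = i))
      }
    }
  }
  run <- run_item(
    provenance = source$path,
    bids = list(acq = "<ProtocolName>", run = "<<1>>", suffix = "unknown"),
    datatype = "extra_data", format_name = source$format_name
  )
  list(matched = FALSE, datatype = "extra_data", run = run, index = NA_integer_)
}

#' Narrow a template run-item to one source data type
#'
#' Returns a copy of `template_run` in which every non-empty attribute
#' pattern is replaced by the source's literal header value (so the
#' narrowed rule makes exact matches only), property patterns are kept
#' verbatim, mapping-time (single bracket) dynamic values in `bids` and
#' `meta` are resolved, coining-time (double bracket) values are kept
#' verbatim, and the provenance records the source path.
#'
#' @param template_run Run-item from a template bidsmap.
#' @param source A [data_source()] for which `match_run()` holds.
#' @return The narrowed (study) run-item.
#' @export
expand_template_run <- function(template_run, source) {
  run <- template_run
  run$provenance <- posix_path(source$path)
  for (key in names(run$attributes)) {
    pat <- run$attributes[[key]]
    if (!is.null(pat) && nzchar(as.character(pat))) {
      run$attributes[[key]] <- get_attribute(source$format_name, source$path, key)
    }
  }
  run$bids <- resolve_mapping(run$bids, source, stage = 1L, used_for = "bids")
  run$meta <- resolve_mapping(run$meta, source, stage = 1L, used_for = "meta")
  run
}

# Resolve every dynamic value of an output dictionary at the given stage.
# Candidate-list values (see the bidsmap model) resolve element-wise,
# keeping the trailing selector index untouched.
resolve_mapping <- function(mapping, source, stage, used_for, quiet = FALSE) {
  for (key in names(mapping)) {
    val <- mapping[[key]]
    if (is.list(val)) {
      n <- length(val)
      for (j in seq_len(max(0L, n - 1L))) {
        val[[j]] <- resolve_value(val[[j]], source, stage, used_for, quiet = quiet)
      }
      mapping[[key]] <- val
    } else {
      mapping[[key]] <- resolve_value(val, source, stage, used_for, quiet = quiet)
    }
  }
  mapping
}
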