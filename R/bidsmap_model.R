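# The bidsmap document model.
#
# A bidsmap is a YAML rule document with an "Options" block (engine and
# plugin settings) followed by one section per source data format. Each
# section carries a dynamic "subject"/"session" label extractor and, per
# BIDS datatype, an ordered list of run-items. A run-item pairs the input
# filters ("properties" over the file system, "attributes" over the file
# header) with the output naming ("bids" entities + suffix) and sidecar
# metadata ("meta"), plus the provenance path of a representative source
# sample. Run-item order is meaningful: it is the matching precedence.

BIDSMAP_RELPATH <- file.path("code", "bidscoin", "bidsmap.yaml")

#' Default location of the study bidsmap inside a BIDS folder
#' @param bidsfolder BIDS output folder.
#' @return `<bidsfolder>/code/bidscoin/bidsmap.yaml`.
#' @export
study_bidsmap_path <- function(bidsfolder) {
  file.path(bidsfolder, BIDSMAP_RELPATH)
}

#' Construct a run-item
#'
#' @param provenance Path of a representative source sample (`""` in a
#'   template).
#' @param properties Named list of regex patterns over the four file
#'   properties; missing keys are filled with `""` (no constraint).
#' @param attributes Named list of regex patterns over header attributes.
#' @param bids Named list of entity values plus a `suffix` key. A value
#'   may be a candidate list: the final element is the 1-based index of
#'   the active candidate.
#' @param meta Named list of sidecar key/values.
#' @param datatype Owning datatype (e.g. `"anat"`); carried on the run
#'   object, encoded by position once stored in a bidsmap.
#' @param format_name Owning data-format section name.
#' @return A named list representing the run-item.
#' @export
run_item <- function(provenance = "", properties = list(), attributes = list(),
                     bids = list(suffix = ""), meta = list(),
                     datatype = NULL, format_name = NULL) {
  props <- stats::setNames(as.list(rep("", 4L)), property_keys())
  for (k in names(properties)) {
    if (!k %in% property_keys()) {
      stop(sprintf("unknown properties key '%s'; allowed keys: %s",
                   k, paste(property_keys(), collapse = ", ")), call. = FALSE)
    }
    props[[k]] <- properties[[k]]
  }
  if (!"suffix" %in% names(bids)) {
    stop("the bids dictionary of a run-item must contain a 'suffix' key",
         call. = FALSE)
  }
  run <- list(provenance = provenance, properties = props,
              attributes = attributes, bids = bids, meta = meta)
  if (!is.null(datatype)) run$datatype <- datatype
  if (!is.null(format_name)) run$format_name <- format_name
  run
}

# Strip the positional fields before storing a run inside a map.
strip_run <- function(run) {
  run$datatype <- NULL
  run$format_name <- NULL
  run
}

# Normalize an input dictionary for identity comparison: non-empty
# patterns only, keys sorted, values as character.
normalize_filters <- function(mapping) {
  if (is.null(mapping) || !length(mapping)) return(character(0))
  vals <- vapply(mapping, function(v) {
    if (is.null(v) || !length(v)) "" else as.character(v)[1]
  }, character(1))
  vals <- vals[nzchar(vals)]
  vals[sort(names(vals), method = "radix")]
}

#' Are two run-items the same source data type?
#'
#' Identity is defined over the input side only — data-format section,
#' datatype, properties, and attributes. Provenance and the user-editable
#' output dictionaries (`bids`, `meta`) are ignored, so edits never cause
#' a run-item to be re-learned as "new".
#'
#' @param a,b Run-items (with `datatype`, and optionally `format_name`,
#'   fields set).
#' @return Logical scalar.
#' @export
runs_equivalent <- function(a, b) {
  identical(a$datatype %||% "", b$datatype %||% "") &&
    identical(a$format_name %||% "", b$format_name %||% "") &&
    identical(normalize_filters(a$properties), normalize_filters(b$properties)) &&
    identical(normalize_filters(a$attributes), normalize_filters(b$attributes))
}

# ---- map accessors ---------------------------------------------------------

#' Options block of a bidsmap
#' @param bidsmap A bidsmap.
#' @return The engine option list (version, bidsignore, prefixes, datatype
#'   classes).
#' @export
bidsmap_options <- function(bidsmap) bidsmap$Options$bidscoin

#' Plugin options block of a bidsmap
#' @param bidsmap A bidsmap.
#' @return Named list of per-plugin option lists.
#' @export
bidsmap_plugins <- function(bidsmap) bidsmap$Options$plugins %||% list()

#' Names of the data-format sections of a bidsmap
#' @param bidsmap A bidsmap.
#' @return Character vector.
#' @export
bidsmap_formats <- function(bidsmap) setdiff(names(bidsmap), "Options")

#' One data-format section of a bidsmap
#' @param bidsmap A bidsmap.
#' @param format Data-format name (e.g. `"Toy"`).
#' @return A list with `subject`, `session`, and `runs` (named list
#'   datatype -> list of run-items), or `NULL` when the section is absent.
#' @export
bidsmap_section <- function(bidsmap, format) {
  sec <- bidsmap[[format]]
  if (is.null(sec)) return(NULL)
  dt <- setdiff(names(sec), c("subject", "session"))
  list(subject = sec$subject %||% "",
       session = sec$session %||% "",
       runs = sec[dt])
}

#' All run-items of a bidsmap, enriched with their position
#'
#' @param bidsmap A bidsmap.
#' @param format Restrict to one data-format section (default: all).
#' @return A flat list of run-items, each carrying `format_name`,
#'   `datatype`, and `index` fields.
#' @export
bidsmap_runs <- function(bidsmap, format = NULL) {
  fmts <- format %||% bidsmap_formats(bidsmap)
  out <- list()
  for (f in fmts) {
    section <- bidsmap_section(bidsmap, f)
    for (dt in names(section$runs)) {
      runs <- section$runs[[dt]]
      for (i in seq_along(runs)) {
        run <- runs[[i]]
        run$format_name <- f
        run$datatype <- dt
        run$index <- i
        out[[length(out) + 1L]] <- run
      }
    }
  }
  out
}

#' Insert a run-item unless an equivalent one is present
#'
#' Appends `run` to its datatype list (created, together with the section,
#' when absent) iff no equivalent run-item — same format, datatype, and
#' input filters, see [runs_equivalent()] — already exists. Insertion at
#' the end preserves the matching precedence of everything already
#' learned.
#'
#' @param bidsmap A bidsmap.
#' @param run A run-item carrying `datatype` and `format_name`.
#' @return A list: `bidsmap` (possibly updated) and `inserted` (flag).
#' @export
insert_run <- function(bidsmap, run) {
  stopifnot(!is.null(run$datatype), !is.null(run$format_name))
  fmt <- run$format_name
  dt <- run$datatype
  if (is.null(bidsmap[[fmt]])) {
    bidsmap[[fmt]] <- list(subject = "", session = "")
  }
  if (is.null(bidsmap[[fmt]][[dt]])) {
    bidsmap[[fmt]][[dt]] <- list()
  }
  existing <- bidsmap[[fmt]][[dt]]
  for (other in existing) {
    other$datatype <- dt
    other$format_name <- fmt
    if (runs_equivalent(run, other)) {
      return(list(bidsmap = bidsmap, inserted = FALSE))
    }
  }
  bidsmap[[fmt]][[dt]] <- c(existing, list(strip_run(run)))
  list(bidsmap = bidsmap, inserted = TRUE)
}

# ---- load / save -----------------------------------------------------------

check_bidsmap_structure <- function(bidsmap, path = "<in-memory>") {
  for (run in bidsmap_runs(bidsmap)) {
    bad <- setdiff(names(run$properties), property_keys())
    if (length(bad)) {
      stop(sprintf(
        "invalid bidsmap '%s': unknown properties key '%s' in %s/%s run %d (allowed: %s)",
        path, bad[1], run$format_name, run$datatype, run$index,
        paste(property_keys(), collapse = ", ")), call. = FALSE)
    }
    if (!"suffix" %in% names(run$bids)) {
      stop(sprintf(
        "invalid bidsmap '%s': missing bids 'suffix' key in %s/%s run %d",
        path, run$format_name, run$datatype, run$index), call. = FALSE)
    }
  }
  invisible(bidsmap)
}

#' Load a bidsmap from YAML
#'
#' Key order and run-item order are preserved. A version string differing
#' from the installed package version is logged as a warning, never an
#' error. Structural problems (an unknown properties key, a run-item
#' without a suffix) are errors.
#'
#' @param path Path to a bidsmap YAML file.
#' @param quiet Suppress console warnings.
#' @return A `bidsmap` object.
#' @export
load_bidsmap <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("bidsmap not found: %s", path), call. = FALSE)
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop(sprintf("could not parse bidsmap YAML '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  bidsmap <- structure(doc, class = "bidsmap")
  check_bidsmap_structure(bidsmap, path)
  installed <- as.character(utils::packageVersion("bidsforge"))
  mapver <- bidsmap_options(bidsmap)$version %||% ""
  if (nzchar(mapver) && !identical(mapver, installed)) {
    bf_warn(sprintf(
      "bidsmap version '%s' differs from the installed version '%s' (%s)",
      mapver, installed, path), quiet = quiet)
  }
  bidsmap
}

#' Save a bidsmap to YAML
#'
#' Serialization is deterministic: key order and run-item order are
#' written exactly as held in memory, so saving twice yields byte-identical
#' files and `load_bidsmap(save_bidsmap(m))` reproduces `m`.
#'
#' @param bidsmap A bidsmap.
#' @param path Output path; parent folders are created.
#' @return `path`, invisibly.
#' @export
save_bidsmap <- function(bidsmap, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  txt <- yaml::as.yaml(unclass(bidsmap), indent = 2,
                       indent.mapping.sequence = TRUE)
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(txt, con, eos = NULL)
    TRUE
  }, error = function(e) {
    stop(sprintf("could not write bidsmap to '%s': %s",
                 path, conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}

#' @export
print.bidsmap <- function(x, ...) {
  opts <- bidsmap_options(x)
  cat(sprintf("<bidsmap> version %s\n", opts$version %||% "?"))
  for (f in bidsmap_formats(x)) {
    section <- bidsmap_section(x, f)
    n <- vapply(section$runs, length, integer(1))
    cat(sprintf("  %s: %d run-item(s) [%s]\n", f, sum(n),
                paste(sprintf("%s %d", names(n), n), collapse = ", ")))
  }
  invisible(x)
}

#' The shipped template bidsmap for the toy scan format
#'
#' The template encodes the broad prior knowledge used for data discovery:
#' localizer/scout protocols are excluded, `mprage`/`T1w` protocols map to
#' anatomical T1w, multiband/multi-echo functional protocols map to func
#' (single-band references first, multi-echo before plain bold), fieldmap
#' protocols split into magnitude/phasediff on the image-type attribute,
#' and a final catch-all run maps anything else to `extra_data`.
#'
#' @return A `bidsmap` object.
#' @export
builtin_template <- function() {
  path <- system.file("extdata", "bidsmap_template.yaml", package = "bidsforge",
                      mustWork = TRUE)
  load_bidsmap(path, quiet = TRUE)
}

# ---- programmatic editing (the headless replacement for a GUI editor) ------

#' Edit run-items in place
#'
#' Applies `bids`/`meta` updates to every run-item of `format` for which
#' `where` returns `TRUE`. This is the programmatic counterpart of editing
#' mappings in a GUI: set task/acquisition labels, fieldmap IntendedFor
#' patterns, and so on, then re-validate with [validate_bidsmap()].
#'
#' @param bidsmap A bidsmap.
#' @param format Data-format section name.
#' @param where Predicate taking an enriched run-item (with `datatype`)
#'   and returning a flag; defaults to all run-items.
#' @param bids,meta Named lists of values to set (a `NULL` value removes
#'   the key).
#' @return The updated bidsmap.
#' @export
edit_run_items <- function(bidsmap, format, where = function(run) TRUE,
                           bids = list(), meta = list()) {
  sec <- bidsmap[[format]]
  if (is.null(sec)) stop(sprintf("no '%s' section in bidsmap", format), call. = FALSE)
  for (dt in setdiff(names(sec), c("subject", "session"))) {
    runs <- sec[[dt]]
    for (i in seq_along(runs)) {
      probe <- runs[[i]]
      probe$datatype <- dt
      probe$format_name <- format
      if (!isTRUE(where(probe))) next
      for (k in names(bids)) runs[[i]]$bids[[k]] <- bids[[k]]
      for (k in names(meta)) runs[[i]]$meta[[k]] <- meta[[k]]
    }
    sec[[dt]] <- runs
  }
  bidsmap[[format]] <- sec
  bidsmap
}

#' Set the subject/session label extractors of a section
#'
#' @param bidsmap A bidsmap.
#' @param format Data-format section name.
#' @param subject,session New dynamic-value text (`NULL` keeps the current
#'   value; set `session = ""` to omit the session level from all output
#'   names).
#' @return The updated bidsmap.
#' @export
set_subject_session <- function(bidsmap, format, subject = NULL, session = NULL) {
  if (is.null(bidsmap[[format]])) {
    stop(sprintf("no '%s' section in bidsmap", format), call. = FALSE)
  }
  if (!is.null(subject)) bidsmap[[format]]$subject <- subject
  if (!is.null(session)) bidsmap[[format]]$session <- session
  bidsmap
}
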