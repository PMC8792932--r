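# BIDS name composition and validation against an embedded schema table.
#
# The schema snapshot (inst/extdata/bids_schema.yaml) fixes the entity
# order and, per datatype, the allowed suffixes/entities and the required
# entities (func requires a task label). validate_run() reproduces the
# green/red feedback of an interactive mapping editor: an empty issue list
# means "green", every issue is one reason the name would be red.

.bf_schema_cache <- new.env(parent = emptyenv())

#' The embedded BIDS schema table
#'
#' @return A list with `entity_order` (character vector) and `datatypes`
#'   (named list with `suffixes`, `entities`, `required`, `extension`).
#' @export
bids_schema <- function() {
  if (is.null(.bf_schema_cache$schema)) {
    path <- system.file("extdata", "bids_schema.yaml", package = "bidsforge",
                        mustWork = TRUE)
    .bf_schema_cache$schema <- yaml::read_yaml(path)
  }
  .bf_schema_cache$schema
}

# Effective value of a bids entry: a candidate list contributes the
# candidate selected by its trailing 1-based integer index; a plain value
# contributes itself.
bids_value <- function(value) {
  if (is.list(value)) {
    n <- length(value)
    if (n < 2L) return("")
    sel <- suppressWarnings(as.integer(value[[n]]))
    if (is.na(sel) || sel < 1L || sel > n - 1L) return("")
    return(as.character(value[[sel]]))
  }
  if (is.null(value) || !length(value)) "" else as.character(value)
}

#' Compose a BIDS output file name
#'
#' Builds `sub-<label>[_ses-<label>]_<entity-label...>_<suffix>` with the
#' entities ordered by the schema (empty values omitted; candidate lists
#' contribute their selected candidate; entities unknown to the schema —
#' possible for BIDS-like datatypes such as `extra_data` — are appended
#' after the schema-ordered ones, in mapping order).
#'
#' @param subject Subject label (without the `sub-` prefix).
#' @param session Session label (`""` omits the session chunk).
#' @param datatype Output datatype (defines entity order scope only).
#' @param bids The bids output dictionary of a run-item (must contain a
#'   non-empty `suffix`).
#' @return The file name, without extension.
#' @export
#' @examples
#' compose_bidsname("001", "", "func",
#'   list(task = "Reward", acq = "mb8", run = "1", suffix = "bold"))
compose_bidsname <- function(subject, session, datatype, bids) {
  suffix <- bids_value(bids[["suffix"]])
  if (!nzchar(suffix)) {
    stop(sprintf("cannot compose a BIDS name without a suffix (datatype '%s')",
                 datatype), call. = FALSE)
  }
  entities <- setdiff(names(bids), "suffix")
  order <- bids_schema()$entity_order
  entities <- c(intersect(order, entities), setdiff(entities, order))
  parts <- paste0("sub-", subject)
  if (nzchar(session)) parts <- c(parts, paste0("ses-", session))
  for (ent in entities) {
    val <- bids_value(bids[[ent]])
    if (nzchar(val)) parts <- c(parts, paste0(ent, "-", val))
  }
  paste(c(parts, suffix), collapse = "_")
}

#' Relative output folder for a BIDS name
#' @param subject,session Labels as in [compose_bidsname()].
#' @param datatype Output datatype (folder name).
#' @return `sub-<label>[/ses-<label>]/<datatype>`.
#' @export
bids_relative_folder <- function(subject, session, datatype) {
  base <- paste0("sub-", subject)
  if (nzchar(session)) base <- file.path(base, paste0("ses-", session))
  file.path(base, datatype)
}

#' Parse a composed BIDS file name
#'
#' Inverse of [compose_bidsname()] on valid names.
#'
#' @param name File name without extension.
#' @return A list with `subject`, `session` (`""` when absent), `entities`
#'   (named character vector), and `suffix`.
#' @export
parse_bidsname <- function(name) {
  chunks <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(chunks) < 2L || !startsWith(chunks[1], "sub-")) {
    stop(sprintf("not a BIDS name: '%s'", name), call. = FALSE)
  }
  subject <- sub("^sub-", "", chunks[1])
  chunks <- chunks[-1]
  session <- ""
  if (length(chunks) && startsWith(chunks[1], "ses-")) {
    session <- sub("^ses-", "", chunks[1])
    chunks <- chunks[-1]
  }
  suffix <- chunks[length(chunks)]
  chunks <- chunks[-length(chunks)]
  entities <- character(0)
  for (ch in chunks) {
    dash <- regexpr("-", ch, fixed = TRUE)
    if (dash < 0L) stop(sprintf("malformed entity chunk '%s' in '%s'", ch, name),
                        call. = FALSE)
    entities[substr(ch, 1L, dash - 1L)] <- substr(ch, dash + 1L, nchar(ch))
  }
  list(subject = subject, session = session, entities = entities,
       suffix = suffix)
}

# Issues for one bids value used as an entity or suffix label. Coining-time
# (double bracket) dynamic chunks are legitimate; mapping-time (single
# bracket) chunks should have been resolved during narrowing; remaining
# literal text must be alphanumeric.
label_issues <- function(key, value, template = FALSE) {
  tokens <- tryCatch(parse_dynamic(value), error = function(e) NULL)
  if (is.null(tokens)) {
    return(sprintf("value of '%s' has unbalanced dynamic-value brackets", key))
  }
  issues <- character(0)
  for (tk in tokens) {
    if (tk$kind == "dynamic") {
      if (tk$level == 1L && !template) {
        issues <- c(issues, sprintf(
          "unresolved mapping-time dynamic value '%s' in '%s'", tk$raw, key))
      }
    } else if (grepl("[^A-Za-z0-9]", tk$raw)) {
      issues <- c(issues, sprintf(
        "invalid characters in '%s' value '%s' (labels must be alphanumeric)",
        key, value))
    }
  }
  issues
}

#' Validate one run-item against the schema
#'
#' Returns the list of problems that would render the previewed output
#' name "red": a missing required entity, an entity or suffix unknown for
#' the datatype, non-alphanumeric label characters, or an unresolved
#' mapping-time dynamic value. Run-items of ignored or BIDS-like datatypes
#' (`ignoretypes`/`unknowntypes`, e.g. `exclude` and `extra_data`) are
#' always valid.
#'
#' @param run A run-item.
#' @param datatype Owning datatype (defaults to the run's own field).
#' @param options Engine options (for `unknowntypes`/`ignoretypes`);
#'   defaults to the shipped template options.
#' @param template In a template, mapping-time (single bracket) dynamic
#'   values are still legitimate — they resolve during narrowing — so they
#'   are not flagged.
#' @return Character vector of issues; `character(0)` means "green".
#' @export
validate_run <- function(run, datatype = run$datatype, options = NULL,
                         template = FALSE) {
  if (is.null(options)) options <- bidsmap_options(builtin_template())
  if (datatype %in% c(options$unknowntypes, options$ignoretypes)) {
    return(character(0))
  }
  schema <- bids_schema()
  spec <- schema$datatypes[[datatype]]
  if (is.null(spec)) {
    return(sprintf("unknown datatype '%s'", datatype))
  }
  issues <- character(0)
  suffix <- bids_value(run$bids[["suffix"]])
  if (!nzchar(suffix)) {
    issues <- c(issues, "missing or empty suffix")
  } else if (!suffix %in% spec$suffixes) {
    issues <- c(issues, sprintf("unknown suffix '%s' for datatype '%s'",
                                suffix, datatype))
  }
  for (ent in setdiff(names(run$bids), "suffix")) {
    val <- bids_value(run$bids[[ent]])
    if (!nzchar(val)) next
    if (!ent %in% spec$entities) {
      issues <- c(issues, sprintf("entity '%s' not allowed for datatype '%s'",
                                  ent, datatype))
    }
    issues <- c(issues, label_issues(ent, val, template = template))
  }
  for (req in spec$required) {
    if (!nzchar(bids_value(run$bids[[req]]))) {
      issues <- c(issues, sprintf("missing required entity '%s'", req))
    }
  }
  issues
}

#' Validate every run-item of a bidsmap
#'
#' The headless counterpart of the editor's green/red overview.
#'
#' @param bidsmap A bidsmap.
#' @param template Validate as a template (see [validate_run()]).
#' @return A tibble with one row per run-item: `format`, `datatype`,
#'   `index`, `provenance`, `n_issues`, `issues` (list column), `valid`.
#' @export
validate_bidsmap <- function(bidsmap, template = FALSE) {
  options <- bidsmap_options(bidsmap)
  runs <- bidsmap_runs(bidsmap)
  rows <- lapply(runs, function(run) {
    found <- validate_run(run, run$datatype, options, template = template)
    tibble::tibble(
      format = run$format_name,
      datatype = run$datatype,
      index = run$index,
      provenance = run$provenance %||% "",
      n_issues = length(found),
      issues = list(found),
      valid = length(found) == 0L
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(format = character(0), datatype = character(0),
                          index = integer(0), provenance = character(0),
                          n_issues = integer(0), issues = list(),
                          valid = logical(0)))
  }
  do.call(rbind, rows)
}
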