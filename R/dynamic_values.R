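# The dynamic-value mini-language.
#
# A bidsmap value is "dynamic" when (parts of) it are captured between
# single (<...>) or double (<<...>>) brackets. The bracketed text names a
# file property or header attribute whose value is substituted in:
#
#   * single brackets resolve at mapping time (while narrowing a template
#     rule into a study rule),
#   * double brackets survive into the study bidsmap and resolve only at
#     coining time (useful for values that vary per subject/session/run).
#
# A colon-separated regular expression may be appended to the key to
# extract a substring, e.g. <<filepath:/sub-(.*?)/>> pulls the subject
# label out of the file path.

#' Parse a templated value into tokens
#'
#' Splits a value into literal and bracketed (dynamic) tokens. A double
#' bracketed token `<<key:pattern>>` has level 2 (coining-time); a single
#' bracketed `<key>` has level 1 (mapping-time). Key and appended pattern
#' are split at the first `":"`. Concatenating the `raw` fields of the
#' returned tokens reproduces the input exactly.
#'
#' @param value Character scalar (non-character input is converted).
#' @return A list of tokens; each token is a list with fields `kind`
#'   (`"literal"` or `"dynamic"`), `raw` (the verbatim slice of the input),
#'   and for dynamic tokens `level` (1 or 2), `key`, and `pattern`
#'   (`NA_character_` when no pattern is appended).
#' @export
#' @examples
#' parse_dynamic("<<filepath:/sub-(.*?)/>>")
#' parse_dynamic("run-<<1>>")
parse_dynamic <- function(value) {
  value <- as.character(value)
  if (length(value) != 1L || is.na(value)) value <- ""
  tokens <- list()
  push_literal <- function(txt) {
    if (nzchar(txt)) {
      tokens[[length(tokens) + 1L]] <<- list(kind = "literal", raw = txt)
    }
  }
  i <- 1L
  n <- nchar(value)
  lit_start <- 1L
  while (i <= n) {
    if (substr(value, i, i) != "<") {
      i <- i + 1L
      next
    }
    dbl <- i + 1L <= n && substr(value, i + 1L, i + 1L) == "<"
    close <- if (dbl) ">>" else ">"
    body_start <- i + (if (dbl) 2L else 1L)
    rest <- substr(value, body_start, n)
    pos <- regexpr(close, rest, fixed = TRUE)
    if (pos < 0L) {
      stop(sprintf("unbalanced bracket at position %d in value '%s'", i, value),
           call. = FALSE)
    }
    push_literal(substr(value, lit_start, i - 1L))
    body <- substr(rest, 1L, pos - 1L)
    raw <- substr(value, i, body_start + pos + nchar(close) - 2L)
    colon <- regexpr(":", body, fixed = TRUE)
    key <- if (colon > 0L) substr(body, 1L, colon - 1L) else body
    pattern <- if (colon > 0L) substr(body, colon + 1L, nchar(body)) else NA_character_
    tokens[[length(tokens) + 1L]] <- list(
      kind = "dynamic", raw = raw,
      level = if (dbl) 2L else 1L,
      key = key, pattern = pattern
    )
    i <- body_start + pos + nchar(close) - 1L
    lit_start <- i
  }
  push_literal(substr(value, lit_start, n))
  tokens
}

#' Extract a substring by regular expression
#'
#' Locates the first match of `pattern` anywhere in `text`. When the
#' pattern contains capture groups, the concatenation of the captured
#' group values is returned; otherwise the whole matched span. No match
#' yields the empty string.
#'
#' @param text Character scalar to search in.
#' @param pattern Regular expression.
#' @return Character scalar (possibly `""`).
#' @export
#' @examples
#' substring_extract("/data/raw/sub-003/ses-01", "/sub-(.*?)/")  # "003"
substring_extract <- function(text, pattern) {
  text <- as.character(text)
  m <- tryCatch(suppressWarnings(regexpr(pattern, text, perl = TRUE)),
                error = function(e) {
                  stop(sprintf("invalid regular expression '%s': %s",
                               pattern, conditionMessage(e)), call. = FALSE)
                })
  if (m < 0L) return("")
  cs <- attr(m, "capture.start")
  if (!is.null(cs) && ncol(cs) > 0L) {
    cl <- attr(m, "capture.length")
    parts <- character(ncol(cs))
    for (j in seq_len(ncol(cs))) {
      parts[j] <- if (cs[1L, j] > 0L) {
        substr(text, cs[1L, j], cs[1L, j] + cl[1L, j] - 1L)
      } else ""
    }
    return(paste0(parts, collapse = ""))
  }
  substr(text, m, m + attr(m, "match.length") - 1L)
}

#' Strip a label down to BIDS-legal characters
#'
#' BIDS entity labels and subject/session labels must be alphanumeric;
#' every other character is removed. Idempotent and never lengthens its
#' input.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' sanitize_label("t1_mprage_sag_p2_iso_1.0")  # "t1mpragesagp2iso10"
sanitize_label <- function(text) {
  gsub("[^A-Za-z0-9]", "", as.character(text))
}

# A purely numeric double-bracket value such as <<1>> is not a key lookup:
# it is the run-index seed, consumed by the coining stage.
is_run_index_token <- function(token) {
  token$kind == "dynamic" && is.na(token$pattern) &&
    grepl("^[0-9]+$", token$key)
}

#' Resolve a templated value against a source file
#'
#' Evaluates the dynamic tokens of `value` whose level is at or below
#' `stage`, looking each key up first among the four file properties
#' (`filepath`, `filename`, `filesize`, `nrfiles`) and then among the
#' source header attributes. An appended pattern triggers substring
#' extraction. Tokens above the stage (and the pure-number run-index seed
#' `<<n>>`) are kept verbatim. Resolved token text destined for a BIDS
#' entity or a subject/session label is sanitized to alphanumerics; meta
#' values keep raw text.
#'
#' @param value The templated value (character scalar).
#' @param source A [data_source()] used for property/attribute lookup.
#' @param stage 1 at mapping time, 2 at coining time.
#' @param used_for `"bids"`, `"subject"`, or `"meta"` — controls label
#'   sanitization.
#' @param quiet Suppress console warnings.
#' @return The resolved character scalar.
#' @export
resolve_value <- function(value, source, stage = 1L,
                          used_for = c("bids", "meta", "subject"),
                          quiet = FALSE) {
  used_for <- match.arg(used_for)
  if (is.list(value) || length(value) != 1L) return(value)
  tokens <- parse_dynamic(value)
  out <- vapply(tokens, function(tk) {
    if (tk$kind == "literal") return(tk$raw)
    if (tk$level > stage || is_run_index_token(tk)) return(tk$raw)
    txt <- source_lookup(source, tk$key, quiet = quiet)
    if (!is.na(tk$pattern)) txt <- substring_extract(txt, tk$pattern)
    if (used_for %in% c("bids", "subject")) txt <- sanitize_label(txt)
    txt
  }, character(1))
  paste0(out, collapse = "")
}

# Property keys shadow attribute keys on a name collision.
source_lookup <- function(source, key, quiet = FALSE) {
  if (key %in% property_keys()) {
    return(extract_property(source, key))
  }
  val <- get_attribute(source$format_name, source$path, key)
  if (!nzchar(val)) {
    bf_warn(sprintf("dynamic key '%s' not found in %s", key, source$path),
            quiet = quiet)
  }
  val
}
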