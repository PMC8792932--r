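# Shared fixture builders: hand-rolled toy files, generated raw trees,
# random bidsmaps, and the independent brute-force matching oracle.

write_toy <- function(path, header = list(), payload = "payloadline") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- c("TOYSCAN/1",
             vapply(names(header), function(k) paste0(k, ": ", header[[k]]),
                    character(1)),
             "---",
             payload)
  writeLines(lines, path)
  path
}

# A one-subject generated study, mapped, edited, ready to coin.
local_example_study <- function(env = parent.frame(), n_subjects = 1,
                                seed = 0) {
  root <- withr::local_tempdir(.local_envir = env)
  raw <- file.path(root, "raw")
  bids <- file.path(root, "bids")
  generate_raw_dataset(raw, n_subjects = n_subjects, seed = seed)
  list(root = root, raw = raw, bids = bids)
}

# md5 per file, names relative to root; log files are append-only by
# design and excluded when `data_only`.
tree_hash <- function(root, data_only = FALSE) {
  files <- list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  if (data_only) {
    files <- files[!grepl("^code/bidscoin/.*\\.(log|errors)$", files)]
  }
  h <- tools::md5sum(file.path(root, files))
  names(h) <- files
  h[order(names(h), method = "radix")]
}

# Independent full-match test: locate the match span with regexpr and
# require it to cover the whole value (rather than anchoring the pattern,
# as the implementation does).
oracle_match_value <- function(pattern, value) {
  if (is.null(pattern) || !nzchar(as.character(pattern))) return(TRUE)
  value <- as.character(value)
  m <- gregexpr(pattern, value, perl = TRUE)[[1]]
  if (m[1] < 0) return(FALSE)
  any(m == 1L & attr(m, "match.length") == nchar(value))
}

oracle_match_run <- function(source, run) {
  for (key in names(run$properties)) {
    pat <- run$properties[[key]]
    if (is.null(pat) || !nzchar(as.character(pat))) next
    if (!oracle_match_value(pat, extract_property(source, key))) return(FALSE)
  }
  for (key in names(run$attributes)) {
    pat <- run$attributes[[key]]
    if (is.null(pat) || !nzchar(as.character(pat))) next
    val <- get_attribute(source$format_name, source$path, key)
    if (!oracle_match_value(pat, val)) return(FALSE)
  }
  TRUE
}

# First-true scan over the flat run list, independent of find_run_match's
# iteration logic.
oracle_first_match <- function(source, bidsmap) {
  for (run in bidsmap_runs(bidsmap, source$format_name)) {
    if (oracle_match_run(source, run)) {
      return(list(datatype = run$datatype, index = run$index))
    }
  }
  list(datatype = "extra_data", index = NA_integer_)
}

# Random generators for property tests --------------------------------------

random_word <- function(n = 8) {
  paste0(sample(c(letters, 0:9), n, replace = TRUE), collapse = "")
}

random_pattern_pool <- function() {
  c("", "", ".*loc.*", "(?i).*t1.*", ".*(mprage|bold).*", "M", "P",
    "[a-z]+[0-9]*", ".*scan.*", "(?i).*(field|map).*", "x{3}")
}

random_bidsmap <- function() {
  skeleton <- list(
    Options = builtin_template()$Options,
    Toy = list(subject = "<<filepath:/sub-(.*?)/>>", session = "")
  )
  map <- structure(skeleton, class = "bidsmap")
  datatypes <- c("exclude", "anat", "func", "extra_data")
  for (dt in sample(datatypes, sample(2:4, 1))) {
    for (i in seq_len(sample(1:3, 1))) {
      run <- run_item(
        provenance = paste0("/raw/sub-001/", random_word(), ".toy"),
        properties = list(filename = sample(c("", ".*\\.toy"), 1)),
        attributes = list(ProtocolName = sample(random_pattern_pool(), 1),
                          ImageTypeText = sample(c("", "M", "P"), 1)),
        bids = list(acq = random_word(5), run = "<<1>>",
                    suffix = sample(c("T1w", "bold", "scan"), 1)),
        meta = list(Comments = "<<PatientComments>>"),
        datatype = dt, format_name = "Toy"
      )
      map <- insert_run(map, run)$bidsmap
    }
  }
  map
}

random_toy_tree <- function(root, n_files = 4) {
  protocols <- c("localizer_32ch", "t1_mprage_sag", "cmrr_bold_scan",
                 "field_map_iso", random_word(10))
  for (i in seq_len(n_files)) {
    write_toy(
      file.path(root, "sub-001", sprintf("%03d-series", i),
                sprintf("%03d_01.toy", i)),
      header = list(ProtocolName = sample(protocols, 1),
                    SeriesNumber = i,
                    SeriesDescription = random_word(6),
                    ImageTypeText = sample(c("M", "P"), 1),
                    PatientComments = "prop test")
    )
  }
  file.path(root, "sub-001")
}
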