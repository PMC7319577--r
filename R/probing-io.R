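#' Parse a QuShape reactivity table
#'
#' QuShape exports a tab-separated table with one row per nucleotide; the
#' sequence lives in the `seqRNA` column. The reactivity column is
#' configurable and defaults to `areaDiff`, QuShape's background-subtracted
#' raw signal, since raw (non-normalized) reactivities are what enters the
#' normalization step. Rows whose reactivity cell is blank or non-numeric
#' become missing positions. Extra columns are ignored.
#'
#' @param x QuShape file path, or its text content (single string with
#'   newlines, or a character vector of lines).
#' @param reactivity_column Name of the column holding raw reactivities.
#' @param probe Probe kind recorded on the returned profile.
#' @param origin Provenance label; defaults to the file name when `x` is a path.
#' @return A raw (non-normalized) [react_profile()].
#' @export
parse_qushape <- function(x, reactivity_column = "areaDiff",
                          probe = c("SHAPE", "DMS", "CMCT"), origin = NULL) {
  probe <- match.arg(probe)
  src <- read_text_lines(x)
  if (is.null(origin)) origin <- src$label
  lines <- src$lines[nzchar(trimws(src$lines))]
  if (!length(lines)) cp_abort("QuShape input is empty", "format_error")

  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  for (col in c("seqRNA", reactivity_column)) {
    if (!col %in% header) {
      cp_abort(sprintf("QuShape input lacks required column '%s'", col),
               "format_error", column = col)
    }
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  grab <- function(col) {
    idx <- match(col, header)
    vapply(cells, function(r) if (idx <= length(r)) r[[idx]] else "", character(1))
  }
  if ("seqNum" %in% header) {
    num <- suppressWarnings(as.integer(grab("seqNum")))
    if (anyNA(num) || any(diff(num) <= 0)) {
      cp_abort("seqNum positions are duplicated or non-monotonic", "format_error")
    }
  }
  nt_raw <- grab("seqRNA")
  nt <- vapply(seq_along(nt_raw), function(i) {
    unclass(rna_sequence(nt_raw[[i]], identifier = "cell"))
  }, character(1))
  val <- suppressWarnings(as.numeric(trimws(grab(reactivity_column))))
  measured <- !is.na(val)

  react_profile(nt, val, measured, probe = probe, normalized = FALSE,
                origin = origin)
}

#' Compare a profile's sequence against a reference
#'
#' Lists every position where the profile's nucleotides differ from the
#' reference sequence, plus any length difference, so inconsistencies
#' between a QuShape file and the input sequence are reported rather than
#' silently accepted.
#'
#' @param profile A [react_profile()].
#' @param reference An [rna_sequence()] (or plain string, canonicalized).
#' @param strict If `TRUE`, any discrepancy raises a reconciliation error
#'   carrying the report.
#' @return A tibble with columns `position`, `profile_nt`, `reference_nt`
#'   (one row per mismatching overlapping position) and attribute
#'   `length_diff` = `nrow(profile) - nchar(reference)`. Empty when the
#'   sequences are identical.
#' @export
reconcile <- function(profile, reference, strict = FALSE) {
  if (!inherits(reference, "rna_seq")) reference <- rna_sequence(reference)
  ref <- seq_chars(reference)
  n <- min(nrow(profile), length(ref))
  if (n == 0) cp_abort("profile and reference must be non-empty", "invalid_profile")
  prof_nt <- profile$nt[seq_len(n)]
  diff <- which(!is.na(prof_nt) & prof_nt != ref[seq_len(n)])
  report <- tibble::tibble(
    position = as.integer(diff),
    profile_nt = prof_nt[diff],
    reference_nt = ref[diff]
  )
  attr(report, "length_diff") <- nrow(profile) - length(ref)
  if (strict && (nrow(report) > 0 || attr(report, "length_diff") != 0)) {
    cp_abort(
      sprintf("sequence reconciliation failed: %d mismatched position(s), length difference %d",
              nrow(report), attr(report, "length_diff")),
      "reconciliation_error", report = report
    )
  }
  report
}

#' Trim a region of interest from a profile
#'
#' Removes flanking positions (for example the primer-binding cassette) from
#' the 5' and 3' ends and renumbers the remainder from 1. The applied 5'
#' offset is retained in the origin label so original coordinates stay
#' recoverable.
#'
#' @param profile A [react_profile()].
#' @param trim5,trim3 Non-negative counts of positions to drop from each end.
#' @return The trimmed [react_profile()].
#' @export
apply_roi <- function(profile, trim5 = 0, trim3 = 0) {
  n <- nrow(profile)
  if (trim5 < 0 || trim3 < 0) cp_abort("trims must be non-negative", "invalid_roi")
  if (trim5 + trim3 >= n) {
    cp_abort(sprintf("ROI trims (%d + %d) remove all %d positions", trim5, trim3, n),
             "empty_roi")
  }
  if (trim5 == 0 && trim3 == 0) return(profile)
  keep <- seq.int(trim5 + 1, n - trim3)
  out <- tibble::as_tibble(profile)[keep, ]
  out$position <- seq_along(keep)
  new_react_profile(out, probe = profile_probe(profile),
                    normalized = is_normalized(profile),
                    origin = sprintf("%s [roi +%d]",
                                     attr(profile, "origin", exact = TRUE), trim5))
}

#' Read a normalized reactivity file
#'
#' The two-column, whitespace-separated dialect used for SHAPE-directed
#' prediction (position, normalized value), where -999 marks positions with
#' unknown reactivity. Positions absent from the file are likewise missing.
#'
#' @param x File path or text content.
#' @param length Declared profile length; defaults to the largest position
#'   in the file (required for empty input).
#' @param sequence Optional [rna_sequence()] supplying the `nt` column.
#' @param probe Probe kind for the returned profile.
#' @return A normalized [react_profile()].
#' @export
read_reactivities <- function(x, length = NULL, sequence = NULL,
                              probe = c("SHAPE", "DMS", "CMCT")) {
  probe <- match.arg(probe)
  src <- read_text_lines(x)
  lines <- src$lines
  keep <- nzchar(trimws(lines))
  pos <- integer(0); val <- numeric(0)
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(fields) != 2) {
      cp_abort(sprintf("line %d: expected two fields, found %d", i, length(fields)),
               "format_error", line = i)
    }
    p <- suppressWarnings(as.integer(fields[[1]]))
    v <- suppressWarnings(as.numeric(fields[[2]]))
    if (is.na(p) || is.na(v)) {
      cp_abort(sprintf("line %d: non-numeric field in '%s'", i, lines[[i]]),
               "format_error", line = i)
    }
    if (p %in% pos) {
      cp_abort(sprintf("line %d: duplicate position %d", i, p), "format_error",
               line = i)
    }
    pos <- c(pos, p); val <- c(val, v)
  }
  if (!is.null(sequence)) {
    if (!inherits(sequence, "rna_seq")) sequence <- rna_sequence(sequence)
    length <- nchar(sequence)
  }
  if (is.null(length)) {
    if (!base::length(pos)) {
      cp_abort("empty reactivity input needs a declared length", "format_error")
    }
    length <- max(pos)
  }
  if (base::length(pos) && (min(pos) < 1 || max(pos) > length)) {
    cp_abort("positions fall outside 1..length", "format_error")
  }
  values <- rep(NA_real_, length)
  values[pos] <- val
  values[values == -999] <- NA_real_
  nt <- if (is.null(sequence)) rep(NA_character_, length) else seq_chars(sequence)
  react_profile(nt, values, probe = probe, normalized = TRUE, origin = src$label)
}

#' Write a normalized reactivity file
#'
#' One line per position: position then value, single-space separated.
#' Values carry 3 decimal places; missing positions are written as the
#' -999 sentinel. `read_reactivities()` of the result reproduces the
#' profile's values (to the written precision) and missing states.
#'
#' @param profile A normalized [react_profile()].
#' @param path Optional output file; when `NULL` the text is returned only.
#' @return The file content, invisibly when `path` is given.
#' @export
write_reactivities <- function(profile, path = NULL) {
  if (!is_normalized(profile)) {
    cp_abort("profile must be normalized before writing a reactivity file",
             "state_error")
  }
  lines <- ifelse(profile$measured,
                  sprintf("%d %.3f", profile$position, profile$reactivity),
                  sprintf("%d -999", profile$position))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

# Accept a path, a single string with newlines, or a vector of lines.
read_text_lines <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(list(lines = readLines(x, warn = FALSE), label = basename(x)))
  }
  list(lines = unlist(strsplit(x, "\n", fixed = TRUE)), label = "text input")
}
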