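#' Canonicalize an RNA sequence
#'
#' Accepts a raw sequence string (optionally FASTA-formatted text with a
#' single record, or a path to such a file), strips whitespace and header
#' lines, upper-cases it and converts T to U. Any character outside
#' `A C G U T` (either case) is rejected with the offending position named.
#'
#' @param raw Sequence text, FASTA text, or a path to a sequence/FASTA file.
#' @param identifier Label for the sequence; a FASTA header, when present,
#'   overrides it.
#' @return A character scalar of class `rna_seq` over the alphabet
#'   `A C G U`, with attribute `id`.
#' @examples
#' rna_sequence("acgt")   # "ACGU"
#' @export
rna_sequence <- function(raw, identifier = "rna") {
  stopifnot(is.character(raw), length(raw) >= 1)
  if (length(raw) == 1 && !grepl("[\n>]", raw) && file.exists(raw)) {
    raw <- readLines(raw, warn = FALSE)
  }
  lines <- unlist(strsplit(raw, "\n", fixed = TRUE))
  header <- grepl("^>", lines)
  if (any(header)) {
    identifier <- sub("^>\\s*", "", lines[which(header)[1]])
    identifier <- sub("\\s.*$", "", identifier)
  }
  seq <- gsub("\\s", "", paste(lines[!header], collapse = ""))
  if (!nzchar(seq)) {
    cp_abort("sequence is empty after removing headers and whitespace",
             "invalid_sequence")
  }
  chars <- toupper(strsplit(seq, "")[[1]])
  bad <- which(!chars %in% c("A", "C", "G", "U", "T"))
  if (length(bad)) {
    cp_abort(
      sprintf("invalid character '%s' at position %d (allowed: A, C, G, U, T)",
              chars[bad[1]], bad[1]),
      "invalid_sequence", position = bad[1]
    )
  }
  chars[chars == "T"] <- "U"
  structure(paste(chars, collapse = ""), id = identifier, class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq> %s (%d nt)\n", attr(x, "id"), nchar(x)))
  cat(strwrap(unclass(x), width = 60), sep = "\n")
  invisible(x)
}

seq_chars <- function(x) strsplit(unclass(x), "")[[1]]
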