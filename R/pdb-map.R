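# Map per-nucleotide reactivities onto the temperature-factor (B-factor)
# field of a PDB structure so any viewer that colours by B-factor shows the
# probing profile in 3D. Editing is strictly column-wise on the fixed-width
# ATOM/HETATM records (B-factor = columns 61-66, "%6.2f"): every byte
# outside those columns survives unchanged, which no generic PDB writer
# guarantees.

#' Match profile positions to PDB chain residues
#'
#' Walks the residues of `chain` in author-numbering order; residue k is
#' matched to profile position `k + offset` when the residue letter equals
#' the profile letter there. Mismatching letters are reported, never mapped
#' silently; more than 10% mismatches aborts with the offending positions.
#'
#' @param pdb Path to a PDB file, or its lines as a character vector.
#' @param profile A [react_profile()].
#' @param chain Chain identifier (single character).
#' @param offset Added to the residue index to obtain the profile position
#'   (use when the construct carries 5' extensions absent from the model).
#' @return A tibble of class `residue_mapping`: `res_seq` (author residue
#'   number), `res_name`, `position` (profile position or `NA`), `matched`;
#'   attributes `chain` and `offset`.
#' @export
match_residues <- function(pdb, profile, chain = "A", offset = 0) {
  lines <- read_pdb_lines(pdb)
  res <- parse_pdb_residues(lines, chain)
  if (nrow(res) == 0) {
    cp_abort(sprintf("chain '%s' not found in PDB input", chain), "lookup_error")
  }
  stopifnot(nrow(profile) >= 1)
  idx <- seq_len(nrow(res)) + offset
  in_range <- idx >= 1 & idx <= nrow(profile)
  letter <- profile$nt[ifelse(in_range, idx, NA_integer_)]
  matched <- in_range & !is.na(letter) & letter == res$res_name
  mapping <- tibble::tibble(
    res_seq = res$res_seq,
    res_name = res$res_name,
    position = ifelse(matched, idx, NA_integer_),
    matched = matched
  )
  mismatch <- which(in_range & !matched)
  if (length(mismatch) > 0.10 * sum(in_range)) {
    cp_abort(
      sprintf("sequence mismatch between profile and chain %s at residues: %s",
              chain, paste(res$res_seq[mismatch], collapse = ", ")),
      "reconciliation_error", residues = res$res_seq[mismatch]
    )
  }
  structure(mapping, chain = chain, offset = offset,
            class = c("residue_mapping", class(mapping)))
}

#' Write reactivities into PDB B-factor columns
#'
#' Every atom of a matched residue receives its profile position's
#' reactivity in columns 61-66 (`%6.2f`); atoms of unmatched residues, and
#' of residues whose position lacks readout, receive -1.00, the display
#' sentinel for absent reactivity. Records of other chains and all
#' non-atom records are untouched, byte for byte.
#'
#' @param pdb Path to a PDB file, or its lines.
#' @param mapping A `residue_mapping` from [match_residues()].
#' @param profile The normalized [react_profile()] the mapping was built
#'   against.
#' @param path Optional output file.
#' @return The modified PDB lines (invisibly when `path` is given).
#' @export
inject_bfactors <- function(pdb, mapping, profile, path = NULL) {
  lines <- read_pdb_lines(pdb)
  chain <- attr(mapping, "chain", exact = TRUE)
  bfac <- function(res_seq) {
    k <- match(res_seq, mapping$res_seq)
    if (is.na(k) || !mapping$matched[k]) return(-1)
    v <- profile$reactivity[mapping$position[k]]
    if (is.na(v)) -1 else v
  }
  n_models <- sum(startsWith(lines, "MODEL"))
  if (n_models > 1) {
    cp_warn("multi-model PDB: B-factors injected in every model record",
            "multi_model")
  }
  out <- lines
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!startsWith(line, "ATOM") && !startsWith(line, "HETATM")) next
    if (nchar(line) < 66) {
      cp_abort(sprintf("line %d: ATOM/HETATM record shorter than 66 columns", ln),
               "format_error", line = ln)
    }
    if (substr(line, 22, 22) != chain) next
    res_seq <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
    if (is.na(res_seq)) {
      cp_abort(sprintf("line %d: unreadable residue number", ln), "format_error",
               line = ln)
    }
    substr(out[[ln]], 61, 66) <- sprintf("%6.2f", bfac(res_seq))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

read_pdb_lines <- function(pdb) {
  stopifnot(is.character(pdb))
  if (length(pdb) == 1 && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE))
}

# Residues of a chain in order of first appearance among ATOM records.
# Residue names are trimmed; standard RNA names are the bare letters.
parse_pdb_residues <- function(lines, chain) {
  atom <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  atom <- atom[nchar(atom) >= 26 & substr(atom, 22, 22) == chain]
  if (!length(atom)) return(tibble::tibble(res_seq = integer(0),
                                           res_name = character(0)))
  res_seq <- as.integer(trimws(substr(atom, 23, 26)))
  res_name <- trimws(substr(atom, 18, 20))
  keep <- !duplicated(res_seq)
  tibble::tibble(res_seq = res_seq[keep], res_name = res_name[keep])
}
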