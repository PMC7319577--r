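# Bracket families recognised in dot-bracket strings, in writing priority
# order. Families beyond '()' encode pseudoknots (crossing pairs).
BRACKET_OPEN  <- c("(", "[", "{", "<", LETTERS)
BRACKET_CLOSE <- c(")", "]", "}", ">", letters)

#' Secondary structures as base-pair tables
#'
#' A secondary structure is a tibble of base pairs with columns `i` and `j`
#' (1-based, `i < j`), attribute `length` (the sequence length) and a
#' `label` naming the method that produced it. Pairs may cross
#' (pseudoknots); no position may occur in more than one pair.
#'
#' @param pairs Data frame with integer columns `i`, `j` (may be empty).
#' @param length Sequence length the pairs live on.
#' @param label Method / provenance label.
#' @return A tibble of class `rna_structure`.
#' @export
rna_structure <- function(pairs, length, label = "structure") {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) pairs <- tibble::tibble(i = integer(0), j = integer(0))
  lo <- as.integer(pmin(pairs$i, pairs$j))
  hi <- as.integer(pmax(pairs$i, pairs$j))
  pairs <- tibble::tibble(i = lo, j = hi)
  pairs <- dplyr::arrange(pairs, .data$i, .data$j)
  if (nrow(pairs)) {
    if (any(pairs$i < 1) || any(pairs$j > length) || any(pairs$i == pairs$j)) {
      cp_abort("base pairs must satisfy 1 <= i < j <= length", "invalid_structure")
    }
    occ <- c(pairs$i, pairs$j)
    if (anyDuplicated(occ)) {
      cp_abort(sprintf("position %d occurs in more than one base pair",
                       occ[duplicated(occ)][1]), "invalid_structure")
    }
  }
  structure(pairs, length = as.integer(length), label = label,
            class = c("rna_structure", class(pairs)))
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %s: %d nt, %d pairs%s\n",
              attr(x, "label", exact = TRUE), attr(x, "length", exact = TRUE),
              nrow(x), if (is_crossing(x)) " (pseudoknotted)" else ""))
  NextMethod()
}

#' @rdname rna_structure
#' @param x An `rna_structure`.
#' @export
structure_length <- function(x) attr(x, "length", exact = TRUE)

# TRUE when any two pairs cross (i1 < i2 < j1 < j2).
is_crossing <- function(x) {
  if (nrow(x) < 2) return(FALSE)
  for (a in seq_len(nrow(x) - 1)) {
    cross <- x$i[a] < x$i & x$i < x$j[a] & x$j[a] < x$j
    if (any(cross)) return(TRUE)
  }
  FALSE
}

#' Parse dot-bracket notation
#'
#' Each bracket family -- `()`, `[]`, `{}`, `<>` and letter pairs `Aa`,
#' `Bb`, ... -- is matched with its own stack, so crossing families encode
#' pseudoknots. Unpaired positions are dots. No minimum hairpin-loop size
#' is enforced: user-supplied structures are taken as given.
#'
#' @param text A dot-bracket string.
#' @param length Optional expected length to validate against.
#' @param label Label for the returned structure.
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("((..[[..))..]]")  # crossing pairs
#' @export
parse_dotbracket <- function(text, length = NULL, label = "structure") {
  chars <- strsplit(trimws(text), "")[[1]]
  n <- base::length(chars)
  if (!is.null(length) && n != length) {
    cp_abort(sprintf("dot-bracket length %d does not match expected %d", n, length),
             "parse_error")
  }
  stacks <- list()
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (p in seq_len(n)) {
    ch <- chars[[p]]
    if (ch == ".") next
    fam_open <- match(ch, BRACKET_OPEN)
    fam_close <- match(ch, BRACKET_CLOSE)
    if (!is.na(fam_open)) {
      key <- as.character(fam_open)
      stacks[[key]] <- c(stacks[[key]], p)
    } else if (!is.na(fam_close)) {
      key <- as.character(fam_close)
      if (!base::length(stacks[[key]])) {
        cp_abort(sprintf("unmatched '%s' at position %d", ch, p), "parse_error",
                 position = p)
      }
      top <- stacks[[key]][base::length(stacks[[key]])]
      stacks[[key]] <- stacks[[key]][-base::length(stacks[[key]])]
      pairs_i <- c(pairs_i, top); pairs_j <- c(pairs_j, p)
    } else {
      cp_abort(sprintf("illegal character '%s' at position %d", ch, p),
               "parse_error", position = p)
    }
  }
  for (key in names(stacks)) {
    if (base::length(stacks[[key]])) {
      fam <- as.integer(key)
      cp_abort(sprintf("unclosed '%s' at position %d", BRACKET_OPEN[fam],
                       stacks[[key]][1]),
               "parse_error", position = stacks[[key]][1])
    }
  }
  rna_structure(tibble::tibble(i = pairs_i, j = pairs_j), length = n, label = label)
}

#' Write dot-bracket notation
#'
#' Inverse of [parse_dotbracket()] on pair sets. Non-crossing structures
#' use only `()`; crossing pairs are layered greedily: pairs are processed
#' in ascending `i` and each is placed in the first bracket family where it
#' crosses no pair already assigned to that family.
#'
#' @param x An [rna_structure()].
#' @return A dot-bracket string of length `structure_length(x)`.
#' @export
write_dotbracket <- function(x) {
  n <- structure_length(x)
  out <- rep(".", n)
  fam_pairs <- vector("list", base::length(BRACKET_OPEN))
  for (k in seq_len(nrow(x))) {
    i <- x$i[k]; j <- x$j[k]
    placed <- FALSE
    for (f in seq_along(fam_pairs)) {
      fp <- fam_pairs[[f]]
      crosses <- FALSE
      if (!is.null(fp)) {
        crosses <- any((fp$i < i & i < fp$j & fp$j < j) |
                       (i < fp$i & fp$i < j & j < fp$j))
      }
      if (!crosses) {
        fam_pairs[[f]] <- rbind(fp, data.frame(i = i, j = j))
        out[i] <- BRACKET_OPEN[f]; out[j] <- BRACKET_CLOSE[f]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cp_abort("structure needs more bracket families than available",
               "capacity_error")
    }
  }
  paste(out, collapse = "")
}

#' Base-pair consensus over structure predictions
#'
#' Counts every base pair across the input predictions and keeps those
#' present in at least `threshold` of them (default half, the "at least
#' 50%" rule). Candidates sharing a nucleotide are resolved
#' deterministically: higher occurrence frequency wins, ties broken by
#' smaller `(i, j)` lexicographically.
#'
#' @param structures List of two or more [rna_structure()]s of equal length.
#' @param threshold Minimum occurrence fraction, in (0, 1].
#' @return An `rna_consensus`: an [rna_structure()]-like tibble with an
#'   extra `frequency` column and attributes `n_inputs` and `threshold`.
#' @export
consensus <- function(structures, threshold = 0.5) {
  if (!is.list(structures) || base::length(structures) < 2) {
    cp_abort("consensus needs at least two input structures", "input_count_error")
  }
  stopifnot(threshold > 0, threshold <= 1)
  lens <- vapply(structures, structure_length, integer(1))
  if (base::length(unique(lens)) != 1) {
    cp_abort("input structures differ in length", "reconciliation_error")
  }
  n_inputs <- base::length(structures)
  counts <- purrr::map_dfr(structures, tibble::as_tibble) |>
    dplyr::count(.data$i, .data$j, name = "n") |>
    dplyr::mutate(frequency = .data$n / n_inputs) |>
    dplyr::filter(.data$frequency >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$i, .data$j)
  taken <- logical(lens[[1]])
  keep <- logical(nrow(counts))
  for (k in seq_len(nrow(counts))) {
    if (!taken[counts$i[k]] && !taken[counts$j[k]]) {
      keep[k] <- TRUE
      taken[c(counts$i[k], counts$j[k])] <- TRUE
    }
  }
  kept <- dplyr::arrange(counts[keep, c("i", "j", "frequency")], .data$i, .data$j)
  out <- rna_structure(kept[c("i", "j")], length = lens[[1]], label = "consensus")
  out$frequency <- kept$frequency[match(paste(out$i, out$j),
                                        paste(kept$i, kept$j))]
  structure(out, n_inputs = n_inputs, threshold = threshold,
            class = c("rna_consensus", class(out)))
}
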