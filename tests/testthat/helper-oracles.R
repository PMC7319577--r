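# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results by the most literal route available (full sorts, explicit
# counting loops) so they share no code path with the implementation.

# Divisor oracle: full descending sort, slice by the ceiling counts, average.
brute_factor <- function(values) {
  n_sel <- ceiling(0.10 * length(values))
  n_exc <- ceiling(0.20 * n_sel)
  sorted <- sort(values, decreasing = TRUE)
  mean(sorted[(n_exc + 1):n_sel])
}

# Consensus oracle: count each pair across all inputs, keep those at or above
# the threshold, then greedily resolve shared nucleotides by frequency, ties
# by lexicographic (i, j).
brute_consensus <- function(structures, threshold = 0.5) {
  all_pairs <- do.call(rbind, lapply(structures, function(s) {
    as.data.frame(s)[c("i", "j")]
  }))
  empty <- data.frame(i = integer(0), j = integer(0), frequency = numeric(0))
  if (is.null(all_pairs) || nrow(all_pairs) == 0) return(empty)
  key <- paste(all_pairs$i, all_pairs$j)
  counts <- table(key)
  freq <- as.numeric(counts) / length(structures)
  keep <- names(counts)[freq >= threshold]
  freq <- freq[freq >= threshold]
  if (!length(keep)) return(empty)
  parts <- do.call(rbind, strsplit(keep, " "))
  cand <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                     frequency = freq)
  cand <- cand[order(-cand$frequency, cand$i, cand$j), ]
  used <- integer(0)
  out <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    if (!(cand$i[r] %in% used) && !(cand$j[r] %in% used)) {
      out <- rbind(out, cand[r, ])
      used <- c(used, cand$i[r], cand$j[r])
    }
  }
  out[order(out$i, out$j), ]
}

# Random non-crossing-per-family structure: repeatedly pick two free
# positions and pair them (crossing allowed across the whole set).
random_structure <- function(len, n_pairs, label = "rand") {
  free <- seq_len(len)
  pairs <- data.frame(i = integer(0), j = integer(0))
  for (k in seq_len(n_pairs)) {
    if (length(free) < 2) break
    pick <- sort(sample(free, 2))
    pairs <- rbind(pairs, data.frame(i = pick[1], j = pick[2]))
    free <- setdiff(free, pick)
  }
  rna_structure(pairs, length = len, label = label)
}

# Minimal fixed-width PDB text for an RNA chain: one P atom per residue.
synthetic_pdb <- function(letters_by_res, chain = "A", start = 1,
                          bfactor = 50) {
  lines <- vapply(seq_along(letters_by_res), function(k) {
    sprintf("ATOM  %5d  P     %s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            k, letters_by_res[k], chain, start + k - 1,
            k * 1.0, k * 2.0, k * 3.0, 1.00, bfactor, "P")
  }, character(1))
  c("HEADER    SYNTHETIC RNA MODEL", lines, "END")
}

hairpin12 <- function() parse_dotbracket("((((....))))", label = "hairpin12")
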