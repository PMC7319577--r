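#' Reactivity profiles
#'
#' A reactivity profile is a tibble with one row per nucleotide position and
#' columns `position` (1-based integer), `nt` (A/C/G/U, or `NA` when the
#' sequence is supplied separately), `reactivity` (numeric; `NA` where the
#' readout is missing) and `measured` (logical). Probe kind, normalization
#' state and provenance ride along as attributes so the profile threads
#' through dplyr pipelines; `new_react_profile()` re-attaches them.
#'
#' Missing positions are a distinct state internally (`measured = FALSE`,
#' `reactivity = NA`), never a sentinel number: writers substitute -999 in
#' reactivity files and -1 in display tables and B-factors.
#'
#' @param nt Character vector of nucleotide letters (or `NA`).
#' @param reactivity Numeric vector, `NA` at missing positions.
#' @param measured Logical vector; defaults to `!is.na(reactivity)`.
#' @param probe One of `"SHAPE"`, `"DMS"`, `"CMCT"`.
#' @param normalized Logical flag: are values on the dimensionless
#'   \[0, 1\] scale?
#' @param origin Free-text label recording where the data came from.
#' @return A tibble of class `react_profile`.
#' @export
react_profile <- function(nt, reactivity, measured = !is.na(reactivity),
                          probe = c("SHAPE", "DMS", "CMCT"),
                          normalized = FALSE, origin = "constructed") {
  probe <- match.arg(probe)
  n <- length(reactivity)
  if (length(nt) != n || length(measured) != n) {
    cp_abort("nt, reactivity and measured must have equal length", "invalid_profile")
  }
  reactivity[!measured] <- NA_real_
  tbl <- tibble::tibble(
    position = seq_len(n),
    nt = as.character(nt),
    reactivity = as.numeric(reactivity),
    measured = as.logical(measured)
  )
  new_react_profile(tbl, probe = probe, normalized = normalized, origin = origin)
}

new_react_profile <- function(tbl, probe, normalized, origin) {
  structure(tbl,
            probe = probe, normalized = normalized, origin = origin,
            class = c("react_profile", class(tibble::as_tibble(tbl))))
}

#' Query profile metadata
#'
#' @param profile A `react_profile`.
#' @return `profile_probe()` the probe kind; `is_normalized()` a logical;
#'   `profile_sequence()` the nucleotide letters collapsed to one string.
#' @export
profile_probe <- function(profile) attr(profile, "probe", exact = TRUE)

#' @rdname profile_probe
#' @export
is_normalized <- function(profile) isTRUE(attr(profile, "normalized", exact = TRUE))

#' @rdname profile_probe
#' @export
profile_sequence <- function(profile) paste(profile$nt, collapse = "")

#' @export
print.react_profile <- function(x, ...) {
  cat(sprintf("<react_profile> probe=%s %s, %d nt (%d measured), origin=%s\n",
              profile_probe(x),
              if (is_normalized(x)) "normalized [0,1]" else "raw",
              nrow(x), sum(x$measured), attr(x, "origin", exact = TRUE)))
  NextMethod()
}

#' Nucleotides susceptible to a chemical probe
#'
#' SHAPE acylates the backbone of every nucleotide; DMS methylates the
#' Watson-Crick face of unpaired A and C; CMCT modifies unpaired G and U.
#'
#' @param probe `"SHAPE"`, `"DMS"` or `"CMCT"`.
#' @return Character vector of susceptible letters.
#' @export
susceptible_letters <- function(probe = c("SHAPE", "DMS", "CMCT")) {
  switch(match.arg(probe),
         SHAPE = c("A", "C", "G", "U"),
         DMS   = c("A", "C"),
         CMCT  = c("G", "U"))
}
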