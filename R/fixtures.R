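# Synthetic probing data with known ground truth. The generator emulates the
# core statistical assumption of chemical probing: nucleotides in
# double-stranded regions are protected from modification, so paired
# positions carry low raw signal and unpaired positions high signal, with
# truncated-Gaussian noise and a sprinkle of positions lacking readout.

#' Reference fixture structures
#'
#' Three versioned secondary structures used throughout the test suite:
#' a 30-nt hairpin, a 40-nt H-type pseudoknot, and a 70-nt three-helix
#' junction with a loop-loop pseudoknot (the topology typical of purine
#' riboswitch aptamers).
#'
#' @return Named list of [rna_structure()]s:
#'   `hairpin30`, `pseudoknot40`, `three_helix70`.
#' @export
fixture_structures <- function() {
  list(
    hairpin30 = parse_dotbracket(
      "((((((((((..........))))))))))", label = "hairpin30"),
    pseudoknot40 = parse_dotbracket(
      "((((....[[[[....))))....]]]]............", label = "pseudoknot40"),
    three_helix70 = parse_dotbracket(
      "(((((..((((((...[[[[)))))).....((((((]]]].....))))))...)))))..........",
      label = "three_helix70")
  )
}

#' Simulate a raw reactivity profile from a known structure
#'
#' Paired positions draw raw signal from N(`paired_mean`, `noise_sd`) and
#' unpaired positions from N(`unpaired_mean`, `noise_sd`), truncated at 0
#' (raw capillary-electrophoresis reactivities are non-negative) and
#' multiplied by `scale` (an arbitrary instrument gain -- invisible after
#' normalization). Each position is independently missing with probability
#' `missing_rate`. A random sequence over A/C/G/U is drawn alongside.
#' Fully reproducible for a fixed `seed`.
#'
#' @param structure An [rna_structure()] giving the ground truth pairing.
#' @param paired_mean,unpaired_mean Mean raw signal of paired/unpaired
#'   positions; signal-bearing fixtures need `unpaired_mean > paired_mean`.
#' @param noise_sd Gaussian noise standard deviation (before truncation).
#' @param missing_rate Probability a position lacks readout, in \[0, 1).
#' @param scale Multiplicative instrument gain.
#' @param seed Integer seed.
#' @param probe Probe kind recorded on the profile.
#' @return A raw [react_profile()] with attribute `paired` (logical ground
#'   truth per position).
#' @export
synth_profile <- function(structure, paired_mean = 1, unpaired_mean = 5,
                          noise_sd = 0.5, missing_rate = 0.05, scale = 1,
                          seed = 1, probe = "SHAPE") {
  n <- structure_length(structure)
  if (is.null(n) || n < 1) cp_abort("structure has length 0", "invalid_structure")
  stopifnot(missing_rate >= 0, missing_rate < 1, scale > 0, noise_sd >= 0)
  paired <- rep(FALSE, n)
  paired[c(structure$i, structure$j)] <- TRUE
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  nt <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  means <- ifelse(paired, paired_mean, unpaired_mean)
  values <- scale * pmax(0, rnorm(n, mean = means, sd = noise_sd))
  measured <- runif(n) >= missing_rate
  out <- react_profile(nt, ifelse(measured, values, NA_real_), measured,
                       probe = probe, normalized = FALSE,
                       origin = sprintf("synthetic(seed=%d)", seed))
  attr(out, "paired") <- paired
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Serialize a profile as a QuShape-style table
#'
#' Emits a tab-separated table with `seqNum`, `seqRNA` and the raw
#' reactivity column (default `areaDiff`); missing positions get a blank
#' reactivity cell. [parse_qushape()] of the result reproduces the
#' profile's letters, values and missing states.
#'
#' @param profile A raw [react_profile()].
#' @param reactivity_column Column name for the reactivity values.
#' @param path Optional output file.
#' @return The file content as a single string, invisibly when written.
#' @export
synth_qushape <- function(profile, reactivity_column = "areaDiff", path = NULL) {
  stopifnot(nrow(profile) >= 1)
  rows <- sprintf("%d\t%s\t%s", profile$position, profile$nt,
                  ifelse(profile$measured,
                         format(profile$reactivity, digits = 15, trim = TRUE,
                                scientific = FALSE),
                         ""))
  text <- paste0(paste(c(sprintf("seqNum\tseqRNA\t%s", reactivity_column), rows),
                       collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

#' In-process mock prediction engine
#'
#' Builds a registry row whose runner never touches an external executable,
#' for testing engine orchestration. `script` maps sequences to outcomes:
#' a named character vector/list (sequence string to dot-bracket; a
#' sequence not in the script is skipped) or a function
#' `function(sequence) dot-bracket`. Scripted `NA` also skips.
#'
#' @param name Engine label.
#' @param script Named character vector/list or a function.
#' @param mode Mode tag recorded on the row.
#' @return A one-row tibble compatible with [run_engine()].
#' @export
mock_engine <- function(name, script, mode = "PREDICT") {
  runner <- function(sequence, reactivities_file, path) {
    db <- if (is.function(script)) {
      script(unclass(sequence))
    } else {
      hit <- match(unclass(sequence), names(script))
      if (is.na(hit)) NA_character_ else script[[hit]]
    }
    if (is.null(db) || is.na(db)) {
      return(list(skip = "no scripted output for this sequence"))
    }
    list(dotbracket = db, raw = db)
  }
  tibble::tibble(name = name, mode = mode, accepts_reactivities = FALSE,
                 exec = "", runner = list(runner))
}
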