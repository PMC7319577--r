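# Adapters around external secondary-structure prediction programs. None is
# bundled: each engine is discovered on PATH (or via an explicit path) and a
# missing executable yields a skipped prediction, never an error, mirroring a
# best-effort multi-method analysis. All engines run with their default
# settings; probing-directed engines receive the reactivity file in the
# dialect written by write_reactivities().

#' Engine registry for an analysis mode
#'
#' SHAPE mode runs the two SHAPE-directed predictors (ViennaRNA RNAfold in
#' its reactivity mode, and ShapeKnots, which can also predict
#' pseudoknots). DMS and CMCT modes run RNAstructure Fold with the matching
#' reactivity option. Prediction mode runs the eight sequence-only methods.
#'
#' @param mode One of `"SHAPE"`, `"DMS"`, `"CMCT"`, `"PREDICT"`.
#' @return A tibble with one row per engine: `name`, `mode`,
#'   `accepts_reactivities`, `exec` (executable hint) and a `runner`
#'   list-column holding the adapter function.
#' @export
engine_registry <- function(mode = c("SHAPE", "DMS", "CMCT", "PREDICT")) {
  mode <- tryCatch(match.arg(mode), error = function(e) {
    cp_abort(sprintf("unknown analysis mode '%s'", mode[1]), "config_error")
  })
  spec <- function(name, exec, accepts, runner) {
    tibble::tibble(name = name, mode = mode, accepts_reactivities = accepts,
                   exec = exec, runner = list(runner))
  }
  switch(mode,
    SHAPE = dplyr::bind_rows(
      spec("RNAfold-SHAPE", "RNAfold", TRUE, run_rnafold),
      spec("ShapeKnots", "ShapeKnots", TRUE, run_shapeknots)
    ),
    DMS = spec("Fold-DMS", "Fold", TRUE, run_rnastructure_fold("-dms")),
    CMCT = spec("Fold-CMCT", "Fold", TRUE, run_rnastructure_fold("-cmct")),
    PREDICT = dplyr::bind_rows(
      spec("RNAfold", "RNAfold", FALSE, run_rnafold),
      spec("Fold", "Fold", FALSE, run_rnastructure_fold(NULL)),
      spec("ProbKnot", "ProbKnot", FALSE, run_probknot),
      spec("CentroidFold", "centroid_fold", FALSE, run_stdout_engine("centroid_fold")),
      spec("CONTRAFold", "contrafold", FALSE, run_contrafold),
      spec("IPknot", "ipknot", FALSE, run_stdout_engine("ipknot")),
      spec("LinearFold-C", "linearfold", FALSE, run_linearfold("-c")),
      spec("LinearFold-V", "linearfold", FALSE, run_linearfold("-V"))
    )
  )
}

#' Run one prediction engine
#'
#' Invokes the engine's external executable with default settings and
#' parses its dot-bracket output against the sequence length. An absent
#' executable gives `status = "skipped"` (with a warning); a non-zero exit
#' or unparseable output gives `status = "failed"` with the captured
#' diagnostics. Input files are never modified.
#'
#' @param engine A one-row tibble from [engine_registry()] (or
#'   [mock_engine()]).
#' @param sequence An [rna_sequence()].
#' @param reactivities_file Path to a normalized reactivity file, required
#'   by probing-directed engines.
#' @param engine_paths Named character vector/list overriding executable
#'   lookup, e.g. `c(RNAfold = "/opt/vienna/bin/RNAfold")`.
#' @return A tibble row: `engine`, `status` (`ok`/`skipped`/`failed`),
#'   `structure` (list-column with an [rna_structure()] or `NULL`),
#'   `detail` (raw output or diagnostic text).
#' @export
run_engine <- function(engine, sequence, reactivities_file = NULL,
                       engine_paths = NULL) {
  stopifnot(nrow(engine) == 1)
  if (!inherits(sequence, "rna_seq")) sequence <- rna_sequence(sequence)
  name <- engine$name[[1]]
  result <- function(status, structure = NULL, detail = "") {
    tibble::tibble(engine = name, status = status,
                   structure = list(structure), detail = detail)
  }
  if (isTRUE(engine$accepts_reactivities[[1]]) && !is.null(reactivities_file) &&
      !file.exists(reactivities_file)) {
    return(result("failed", detail = "reactivity file not found"))
  }
  runner <- engine$runner[[1]]
  exec <- engine$exec[[1]]
  path <- resolve_executable(exec, engine_paths)
  if (is.na(exec) || is.null(runner)) {
    return(result("failed", detail = "engine has no runner"))
  }
  if (!identical(exec, "") && is.null(path)) {
    cp_warn(sprintf("engine %s: executable '%s' not found; skipping", name, exec),
            "engine_skipped")
    return(result("skipped", detail = sprintf("executable '%s' not found", exec)))
  }
  out <- tryCatch(
    runner(sequence, reactivities_file, path),
    error = function(e) list(error = conditionMessage(e))
  )
  if (!is.null(out$skip)) {
    cp_warn(sprintf("engine %s: %s; skipping", name, out$skip), "engine_skipped")
    return(result("skipped", detail = out$skip))
  }
  if (!is.null(out$error)) return(result("failed", detail = out$error))
  db <- out$dotbracket
  structure <- tryCatch(
    parse_dotbracket(db, length = nchar(sequence), label = name),
    error = function(e) e
  )
  if (inherits(structure, "error")) {
    return(result("failed",
                  detail = sprintf("unparseable output: %s",
                                   conditionMessage(structure))))
  }
  result("ok", structure = structure, detail = out$raw %||% db)
}

#' Run every engine of a registry
#'
#' @inheritParams run_engine
#' @param registry Tibble from [engine_registry()] (mock rows allowed).
#' @return A tibble with one prediction row per engine, in registry order.
#' @export
run_engines <- function(registry, sequence, reactivities_file = NULL,
                        engine_paths = NULL) {
  purrr::map_dfr(seq_len(nrow(registry)), function(k) {
    run_engine(registry[k, ], sequence, reactivities_file, engine_paths)
  })
}

resolve_executable <- function(exec, engine_paths = NULL) {
  if (is.null(exec) || is.na(exec) || !nzchar(exec)) return(NULL)
  override <- engine_paths[[exec]]
  if (!is.null(override)) {
    return(if (file.exists(override)) override else NULL)
  }
  hit <- Sys.which(exec)
  if (nzchar(hit)) unname(hit) else NULL
}

# ---- individual adapters ---------------------------------------------------
# Each runner returns list(dotbracket=, raw=) on success, list(error=) on a
# tool failure, or list(skip=) when a required companion tool is absent.

run_rnafold <- function(sequence, reactivities_file, path) {
  args <- "--noPS"
  if (!is.null(reactivities_file)) {
    args <- c(args, sprintf("--shape=%s", reactivities_file))
  }
  out <- suppressWarnings(system2(path, args, input = unclass(sequence),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    return(list(error = sprintf("RNAfold exit %d: %s", status,
                                paste(out, collapse = " "))))
  }
  list(dotbracket = extract_dotbracket_line(out, nchar(sequence)),
       raw = paste(out, collapse = "\n"))
}

# RNAstructure engines write CT files; ct2dot converts to dot-bracket.
run_rnastructure_fold <- function(probe_flag) {
  function(sequence, reactivities_file, path) {
    run_ct_engine(path, sequence, function(seq_file, ct_file) {
      args <- c(seq_file, ct_file, "-mfe")
      if (!is.null(probe_flag) && !is.null(reactivities_file)) {
        args <- c(args, probe_flag, reactivities_file)
      }
      args
    })
  }
}

run_probknot <- function(sequence, reactivities_file, path) {
  run_ct_engine(path, sequence,
                function(seq_file, ct_file) c(seq_file, ct_file, "--sequence"))
}

run_shapeknots <- function(sequence, reactivities_file, path) {
  run_ct_engine(path, sequence, function(seq_file, ct_file) {
    args <- c(seq_file, ct_file)
    if (!is.null(reactivities_file)) args <- c(args, "-sh", reactivities_file)
    args
  })
}

run_ct_engine <- function(path, sequence, make_args) {
  seq_file <- tempfile(fileext = ".fasta")
  ct_file <- tempfile(fileext = ".ct")
  on.exit(unlink(c(seq_file, ct_file)), add = TRUE)
  writeLines(c(">query", unclass(sequence)), seq_file)
  out <- suppressWarnings(system2(path, make_args(seq_file, ct_file),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0 || !file.exists(ct_file)) {
    return(list(error = sprintf("exit %d: %s", status, paste(out, collapse = " "))))
  }
  ct <- readLines(ct_file, warn = FALSE)
  list(dotbracket = ct_to_dotbracket(ct), raw = paste(ct, collapse = "\n"))
}

run_contrafold <- function(sequence, reactivities_file, path) {
  seq_file <- tempfile(fileext = ".fasta")
  on.exit(unlink(seq_file), add = TRUE)
  writeLines(c(">query", unclass(sequence)), seq_file)
  out <- suppressWarnings(system2(path, c("predict", seq_file),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    return(list(error = sprintf("exit %d: %s", status, paste(out, collapse = " "))))
  }
  list(dotbracket = extract_dotbracket_line(out, nchar(sequence)),
       raw = paste(out, collapse = "\n"))
}

run_linearfold <- function(flag) {
  function(sequence, reactivities_file, path) {
    out <- suppressWarnings(system2(path, flag, input = unclass(sequence),
                                    stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0) {
      return(list(error = sprintf("exit %d: %s", status,
                                  paste(out, collapse = " "))))
    }
    list(dotbracket = extract_dotbracket_line(out, nchar(sequence)),
         raw = paste(out, collapse = "\n"))
  }
}

run_stdout_engine <- function(tool) {
  function(sequence, reactivities_file, path) {
    seq_file <- tempfile(fileext = ".fasta")
    on.exit(unlink(seq_file), add = TRUE)
    writeLines(c(">query", unclass(sequence)), seq_file)
    out <- suppressWarnings(system2(path, seq_file, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0) {
      return(list(error = sprintf("exit %d: %s", status,
                                  paste(out, collapse = " "))))
    }
    list(dotbracket = extract_dotbracket_line(out, nchar(sequence)),
         raw = paste(out, collapse = "\n"))
  }
}

# First whitespace-delimited token of the expected length built from
# dot-bracket characters, anywhere in the tool's stdout.
extract_dotbracket_line <- function(lines, n) {
  tokens <- unlist(strsplit(lines, "\\s+"))
  ok <- grepl("^[.()\\[\\]{}<>A-Za-z]+$", tokens, perl = TRUE) &
    nchar(tokens) == n & grepl("[.()\\[\\]{}<>]", tokens, perl = TRUE)
  if (!any(ok)) stop("no dot-bracket line of the expected length in output")
  tokens[which(ok)[1]]
}

#' Convert CT-format pairing output to dot-bracket
#'
#' CT files (used by the RNAstructure programs) carry one row per
#' nucleotide: index, letter, neighbours, pairing partner (0 = unpaired),
#' original index. Only the first structure record is converted.
#'
#' @param lines Character vector of CT file lines.
#' @return A dot-bracket string.
#' @export
ct_to_dotbracket <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) cp_abort("empty CT input", "format_error")
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[[1]]))
  if (is.na(n) || length(lines) < n + 1) {
    cp_abort("malformed CT header", "format_error")
  }
  rows <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  idx <- vapply(rows, function(r) as.integer(r[[1]]), integer(1))
  partner <- vapply(rows, function(r) as.integer(r[[5]]), integer(1))
  keep <- partner > idx
  write_dotbracket(rna_structure(
    tibble::tibble(i = idx[keep], j = partner[keep]), length = n, label = "ct"))
}
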