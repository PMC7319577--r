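#' Configure an analysis run
#'
#' Bundles and validates everything one run needs. Probing modes (`shape`,
#' `dms`, `cmct`) require QuShape input or a pre-normalized reactivity
#' file; `predict` mode forbids both and works from the sequence alone.
#' The default length cap of 600 nt reflects the declining accuracy of
#' secondary-structure prediction on long RNAs; it can be raised
#' explicitly (`max_len`) at the user's own risk.
#'
#' @param mode `"shape"`, `"dms"`, `"cmct"` or `"predict"`.
#' @param sequence Sequence text/path (see [rna_sequence()]).
#' @param outdir Output directory (created if needed).
#' @param qushape Character vector of QuShape file paths (replicates).
#' @param reactivities Path to a pre-normalized reactivity file.
#' @param trim5,trim3 Region-of-interest trims (e.g. the cassette).
#' @param nt_specific Use probe-susceptible nucleotides only for the
#'   normalization divisor (DMS/CMCT).
#' @param structure Optional user dot-bracket string or file.
#' @param pdb,chain,offset Optional PDB input for B-factor mapping.
#' @param engines Optional engine registry tibble (defaults to
#'   [engine_registry()] for the mode; pass [mock_engine()] rows for
#'   testing).
#' @param engine_paths Named executable-path overrides.
#' @param max_len Maximum accepted sequence length.
#' @param strict Abort on any sequence reconciliation mismatch.
#' @param scheme Heatmap colour scheme override.
#' @param grey_out Grey out non-susceptible nucleotides in VARNA exports.
#' @param reactivity_column QuShape column holding raw reactivities.
#' @param job Job name used in tables and file names.
#' @return A validated list of class `probe_config`.
#' @export
probe_config <- function(mode, sequence, outdir,
                         qushape = character(), reactivities = NULL,
                         trim5 = 0, trim3 = 0, nt_specific = FALSE,
                         structure = NULL, pdb = NULL, chain = "A", offset = 0,
                         engines = NULL, engine_paths = NULL,
                         max_len = 600, strict = FALSE, scheme = NULL,
                         grey_out = FALSE, reactivity_column = "areaDiff",
                         job = "job") {
  mode <- match.arg(tolower(mode), c("shape", "dms", "cmct", "predict"))
  probing <- mode != "predict"
  has_input <- length(qushape) > 0 || !is.null(reactivities)
  if (probing && !has_input) {
    cp_abort(sprintf("%s mode requires QuShape or reactivity-file input", mode),
             "config_error")
  }
  if (!probing && has_input) {
    cp_abort("predict mode takes no probing input", "config_error")
  }
  if (length(qushape) > 0 && !is.null(reactivities)) {
    cp_abort("supply either QuShape files or a reactivity file, not both",
             "config_error")
  }
  structure(
    list(mode = mode, sequence = sequence, outdir = outdir, qushape = qushape,
         reactivities = reactivities, trim5 = trim5, trim3 = trim3,
         nt_specific = nt_specific, structure = structure, pdb = pdb,
         chain = chain, offset = offset, engines = engines,
         engine_paths = engine_paths, max_len = max_len, strict = strict,
         scheme = scheme, grey_out = grey_out,
         reactivity_column = reactivity_column, job = job),
    class = "probe_config"
  )
}

#' Run a configured analysis
#'
#' Probing modes: parse each QuShape replicate, reconcile against the
#' input sequence, trim the region of interest, normalize each replicate,
#' average, write the reactivity file, run the mode's prediction engines
#' on the averaged profile, and render the heatmap, barplot, VARNA exports
#' (including a user-supplied structure, if any) and the B-factor-mapped
#' PDB, plus the results table and all-predictions text file. Predict
#' mode: run the eight sequence-only engines, build the base-pair
#' consensus over the successful predictions, and emit structure outputs
#' only (no reactivity artifacts).
#'
#' @param config A [probe_config()].
#' @return A `result_bundle`: list with the normalized `profile` (probing
#'   modes), `norm` fit, `predictions` tibble, `consensus` (predict mode),
#'   `table` (the results tibble), `manifest` of files written, and `log`
#'   lines.
#' @export
probe_run <- function(config) {
  stopifnot(inherits(config, "probe_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logline <- character(0)
  note <- function(...) logline <<- c(logline, sprintf(...))
  outfile <- function(name) file.path(config$outdir, paste0(config$job, ".", name))
  manifest <- character(0)

  sequence <- rna_sequence(config$sequence, identifier = config$job)
  if (nchar(sequence) > config$max_len) {
    cp_abort(sprintf("sequence length %d: cannot exceed %d nucleotides",
                     nchar(sequence), config$max_len), "length_error")
  }
  roi_seq <- sequence
  if (config$trim5 > 0 || config$trim3 > 0) {
    chars <- seq_chars(sequence)
    keep <- seq.int(config$trim5 + 1, length(chars) - config$trim3)
    roi_seq <- rna_sequence(paste(chars[keep], collapse = ""),
                            identifier = attr(sequence, "id"))
  }
  probing <- config$mode != "predict"
  probe <- toupper(config$mode)
  profile <- NULL; norm <- NULL

  if (probing) {
    if (length(config$qushape) > 0) {
      reps <- purrr::map(config$qushape, function(f) {
        p <- parse_qushape(f, reactivity_column = config$reactivity_column,
                           probe = probe)
        rep_report <- reconcile(p, sequence, strict = config$strict)
        if (nrow(rep_report) || attr(rep_report, "length_diff") != 0) {
          note("reconciliation: %s has %d mismatch(es), length diff %d",
               basename(f), nrow(rep_report), attr(rep_report, "length_diff"))
        }
        apply_roi(p, config$trim5, config$trim3)
      })
      if (length(reps) > 1) {
        ref_seq <- profile_sequence(reps[[1]])
        for (p in reps[-1]) {
          if (!identical(profile_sequence(p), ref_seq)) {
            cp_abort("replicate QuShape files disagree in sequence after ROI trimming",
                     "reconciliation_error")
          }
        }
      }
      norms <- purrr::map(reps, normalize_profile,
                          nucleotide_specific = config$nt_specific)
      for (k in seq_along(norms)) {
        note("normalization[%d]: factor %.4f from %d values (%s)", k,
             norms[[k]]$factor, norms[[k]]$n_measured, norms[[k]]$subset)
      }
      norm <- norms[[1]]
      profile <- if (length(norms) > 1) {
        average_profiles(purrr::map(norms, "profile"))
      } else norms[[1]]$profile
    } else {
      profile <- read_reactivities(config$reactivities, sequence = roi_seq,
                                   probe = probe)
      note("pre-normalized reactivities read from %s", config$reactivities)
    }
    react_file <- outfile("reactivities.txt")
    write_reactivities(profile, react_file)
    manifest <- c(manifest, react_file)
  }

  registry <- config$engines %||% engine_registry(toupper(
    if (probing) config$mode else "predict"))
  react_arg <- if (probing) outfile("reactivities.txt") else NULL
  predictions <- run_engines(registry, roi_seq, react_arg, config$engine_paths)
  for (k in seq_len(nrow(predictions))) {
    note("engine %s: %s", predictions$engine[k], predictions$status[k])
  }
  ok <- predictions[predictions$status == "ok", ]
  if (probing && nrow(ok) == 0) {
    cp_warn("all probing-mode engines were skipped or failed; structure outputs absent",
            "no_predictions")
  }

  cons <- NULL
  if (!probing && nrow(ok) >= 2) {
    cons <- consensus(ok$structure)
    note("consensus: %d pairs from %d predictions", nrow(cons), nrow(ok))
  }

  user_structure <- NULL
  if (!is.null(config$structure)) {
    text <- if (file.exists(config$structure)) {
      paste(readLines(config$structure, warn = FALSE), collapse = "")
    } else config$structure
    user_structure <- parse_dotbracket(text, length = nchar(roi_seq),
                                       label = "user")
  }

  if (probing) {
    heat <- plot_reactivity_heatmap(profile,
                                    scheme = config$scheme %||% probe)
    manifest <- c(manifest, save_plot_pair(heat, outfile("heatmap")))
    bars <- plot_reactivity_barplot(profile)
    manifest <- c(manifest, save_plot_pair(bars, outfile("barplot")))
  }

  varna_targets <- c(
    purrr::set_names(ok$structure, ok$engine),
    if (!is.null(user_structure)) list(user = user_structure),
    if (!is.null(cons)) list(consensus = cons)
  )
  for (nm in names(varna_targets)) {
    for (layout in c("radiate", "circular", "linear")) {
      ex <- varna_export(varna_targets[[nm]], profile = profile, layout = layout,
                         grey_out = config$grey_out,
                         stem = file.path(config$outdir,
                                          sprintf("%s.%s.%s", config$job, nm, layout)))
      manifest <- c(manifest, ex$files)
    }
  }

  if (!is.null(config$pdb) && probing) {
    mapping <- match_residues(config$pdb, profile, chain = config$chain,
                              offset = config$offset)
    pdb_out <- outfile("bfactors.pdb")
    inject_bfactors(config$pdb, mapping, profile, path = pdb_out)
    manifest <- c(manifest, pdb_out)
    note("pdb: %d/%d residues matched on chain %s",
         sum(mapping$matched), nrow(mapping), config$chain)
  }

  bundle <- structure(
    list(mode = config$mode, job = config$job, sequence = roi_seq,
         profile = profile, norm = norm, predictions = predictions,
         consensus = cons, user_structure = user_structure,
         table = NULL, manifest = manifest, log = logline,
         outdir = config$outdir),
    class = "result_bundle"
  )
  bundle$table <- results_table(bundle)
  manifest <- c(manifest,
                write_results_table(bundle, outfile("table")),
                write_all_predictions(bundle, outfile("predictions.txt")))
  if (nrow(ok) || !is.null(user_structure)) {
    chosen <- if (!is.null(user_structure)) user_structure else ok$structure[[1]]
    sim_file <- outfile("structure-for-3d.txt")
    writeLines(c(unclass(roi_seq), write_dotbracket(chosen)), sim_file)
    manifest <- c(manifest, sim_file)
  }
  log_file <- outfile("log.txt")
  writeLines(logline, log_file)
  bundle$manifest <- c(manifest, log_file)
  bundle$log <- logline
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> mode=%s job=%s: %d prediction(s), %d file(s)\n",
              x$mode, x$job, sum(x$predictions$status == "ok"),
              length(x$manifest)))
  invisible(x)
}

# The five-part results table: Name, Method, Filename, Full_string, then one
# per-nucleotide cell per position holding "letter value bracket" (value -1
# when the readout is missing; bracket "." when no structure applies).
results_table <- function(bundle) {
  n <- nchar(bundle$sequence)
  chars <- seq_chars(bundle$sequence)
  vals <- if (!is.null(bundle$profile)) {
    ifelse(bundle$profile$measured,
           sprintf("%.3f", bundle$profile$reactivity), "-1")
  } else rep(NA_character_, n)
  cell_row <- function(method, full, brackets) {
    cells <- paste(chars,
                   if (all(is.na(vals))) "" else vals,
                   brackets)
    cells <- trimws(gsub("\\s+", " ", cells))
    row <- c(list(Name = bundle$job, Method = method,
                  Filename = sprintf("%s_%s", bundle$job, bundle$mode),
                  Full_string = full),
             purrr::set_names(as.list(cells), paste0("nt", seq_len(n))))
    tibble::as_tibble(row)
  }
  rows <- list(cell_row("sequence", unclass(bundle$sequence), rep("", n)))
  if (!is.null(bundle$profile)) {
    rows <- c(rows, list(cell_row("reactivity",
                                  paste(vals, collapse = " "), rep("", n))))
  }
  ok <- bundle$predictions[bundle$predictions$status == "ok", ]
  for (k in seq_len(nrow(ok))) {
    db <- write_dotbracket(ok$structure[[k]])
    rows <- c(rows, list(cell_row(ok$engine[[k]], db, strsplit(db, "")[[1]])))
  }
  if (!is.null(bundle$user_structure)) {
    db <- write_dotbracket(bundle$user_structure)
    rows <- c(rows, list(cell_row("user", db, strsplit(db, "")[[1]])))
  }
  if (!is.null(bundle$consensus)) {
    db <- write_dotbracket(bundle$consensus)
    rows <- c(rows, list(cell_row("consensus", db, strsplit(db, "")[[1]])))
  }
  dplyr::bind_rows(rows)
}

#' Write the results table
#'
#' The table is written in two flavors with identical content: CSV (the
#' spreadsheet format) and tab-delimited text. Each row describes one
#' method/record kind; the five parts are the job name, method, file name,
#' the full sequence/structure string, and one cell per nucleotide holding
#' letter, reactivity (-1 when missing) and dot-bracket character.
#'
#' @param bundle A `result_bundle`.
#' @param stem Output path without extension.
#' @return Character vector of files written.
#' @export
write_results_table <- function(bundle, stem) {
  tab <- bundle$table %||% results_table(bundle)
  lens <- nchar(tab$Full_string[tab$Method != "reactivity"])
  if (length(lens) && any(lens != nchar(bundle$sequence))) {
    cp_abort("results table rows inconsistent with sequence length",
             "internal_error")
  }
  csv <- paste0(stem, ".csv")
  txt <- paste0(stem, ".txt")
  readr::write_csv(tab, csv)
  readr::write_tsv(tab, txt)
  c(csv, txt)
}

#' Write the all-predictions text file
#'
#' The sequence on the first line, then one labeled dot-bracket line per
#' successful prediction (structure, a space, the method name). Skipped or
#' failed methods are listed in a trailing comment block. With zero
#' successful predictions the file still carries the sequence plus a
#' notice, and a warning is logged.
#'
#' @param bundle A `result_bundle`.
#' @param path Output file.
#' @return `path`, invisibly usable in manifests.
#' @export
write_all_predictions <- function(bundle, path) {
  ok <- bundle$predictions[bundle$predictions$status == "ok", ]
  lines <- unclass(bundle$sequence)
  for (k in seq_len(nrow(ok))) {
    lines <- c(lines, paste(write_dotbracket(ok$structure[[k]]), ok$engine[[k]]))
  }
  if (!is.null(bundle$consensus)) {
    lines <- c(lines, paste(write_dotbracket(bundle$consensus), "consensus"))
  }
  if (nrow(ok) == 0) {
    cp_warn("no successful predictions to write", "no_predictions")
    lines <- c(lines, "# no successful predictions")
  }
  rest <- bundle$predictions[bundle$predictions$status != "ok", ]
  if (nrow(rest)) {
    lines <- c(lines, "#",
               sprintf("# %s: %s (%s)", rest$status, rest$engine, rest$detail))
  }
  writeLines(lines, path)
  path
}
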