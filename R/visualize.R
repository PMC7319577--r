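# Reactivity visualization: per-nucleotide heatmap, binned barplot, and
# VARNA-compatible exports. Colour assignment is a pure function of
# (value, scheme); missing positions always render in a neutral grey that
# no ramp can produce.

MISSING_COLOR <- "#BDBDBD"

#' Colour schemes for reactivity heatmaps
#'
#' Default ramps per probe: SHAPE yellow-orange-red, DMS yellow-green,
#' CMCT white-red; plus named alternatives the user may pick instead.
#' Every ramp maps \[0, 1\] monotonically.
#'
#' @return Named list of character vectors of ramp anchor colours.
#' @export
color_schemes <- function() {
  list(
    SHAPE = c("#FFFFCC", "#FD8D3C", "#E31A1C"),
    DMS   = c("#FFFFCC", "#A1DAB4", "#238443"),
    CMCT  = c("#FFFFFF", "#FB6A4A", "#CB181D"),
    viridis = c("#440154", "#21908C", "#FDE725"),
    blues   = c("#F7FBFF", "#6BAED6", "#08306B"),
    greys   = c("#FFFFFF", "#878787", "#1A1A1A")
  )
}

#' Map normalized reactivities to colours
#'
#' @param values Numeric vector in \[0, 1\]; `NA` = missing.
#' @param scheme A scheme name from [color_schemes()] or a vector of ramp
#'   anchor colours.
#' @return Character vector of hex colours; missing values get the grey
#'   missing colour.
#' @export
reactivity_colors <- function(values, scheme = "SHAPE") {
  anchors <- if (is.character(scheme) && length(scheme) == 1) {
    color_schemes()[[scheme]] %||%
      cp_abort(sprintf("unknown colour scheme '%s'", scheme), "config_error")
  } else scheme
  ramp <- grDevices::colorRamp(anchors)
  out <- rep(MISSING_COLOR, length(values))
  ok <- !is.na(values)
  if (any(ok)) {
    rgb <- ramp(pmin(1, pmax(0, values[ok])))
    out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  out
}

#' Reactivity heatmap
#'
#' One coloured box per nucleotide, wrapped into rows of `wrap` positions,
#' annotated with the nucleotide letter and periodic position labels.
#' Missing positions are grey.
#'
#' @param profile A normalized [react_profile()].
#' @param scheme Scheme name or anchor colours; defaults to the profile's
#'   probe-specific ramp.
#' @param wrap Boxes per row.
#' @param label_every Interval of position labels along each row.
#' @return A ggplot object.
#' @export
plot_reactivity_heatmap <- function(profile, scheme = NULL, wrap = 50,
                                    label_every = 10) {
  if (!is_normalized(profile)) cp_abort("profile must be normalized", "state_error")
  scheme <- scheme %||% profile_probe(profile)
  dat <- tibble::as_tibble(profile) |>
    dplyr::mutate(
      row = (.data$position - 1) %/% wrap,
      col = (.data$position - 1) %% wrap + 1,
      fill = reactivity_colors(.data$reactivity, scheme),
      lab = ifelse(.data$position %% label_every == 0,
                   as.character(.data$position), "")
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill),
                       colour = "white", linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$nt), size = 2.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), vjust = -2.1, size = 2) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse(expand = ggplot2::expansion(add = 0.6)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s reactivity", profile_probe(profile)))
}

#' Reactivity barplot
#'
#' One bar per position, height equal to the normalized value, coloured by
#' the conventional bins: black on \[0, 0.3), orange on \[0.3, 0.7), red on
#' \[0.7, 1\] (bins are left-closed, so 0.3 is orange and 0.7 red).
#' Missing positions get no bar, only a grey tick at the axis.
#'
#' @param profile A normalized [react_profile()].
#' @return A ggplot object.
#' @export
plot_reactivity_barplot <- function(profile) {
  if (!is_normalized(profile)) cp_abort("profile must be normalized", "state_error")
  dat <- tibble::as_tibble(profile) |>
    dplyr::mutate(fill = reactivity_bin_color(.data$reactivity))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_col(
      data = function(d) d[!is.na(d$reactivity), ],
      ggplot2::aes(y = .data$reactivity, fill = .data$fill), width = 0.8) +
    ggplot2::geom_point(
      data = function(d) d[is.na(d$reactivity), ],
      ggplot2::aes(y = 0), shape = 3, colour = MISSING_COLOR, size = 1) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position", y = "normalized reactivity") +
    ggplot2::theme_classic()
}

#' Bin colour of a normalized reactivity
#'
#' @param values Numeric vector in \[0, 1\] (`NA` = missing).
#' @return `"black"`, `"orange"`, `"red"`, or the missing grey.
#' @export
reactivity_bin_color <- function(values) {
  dplyr::case_when(
    is.na(values) ~ MISSING_COLOR,
    values < 0.3 ~ "black",
    values < 0.7 ~ "orange",
    TRUE ~ "red"
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.react_profile <- function(object, ...) plot_reactivity_barplot(object)

#' @exportS3Method ggplot2::autoplot
autoplot.react_norm <- function(object, ...) plot_reactivity_barplot(object$profile)

#' Save a plot as PNG and SVG
#'
#' @param plot A ggplot object.
#' @param stem Output path without extension.
#' @param width,height,dpi Device geometry.
#' @return Character vector of the two files written.
#' @export
save_plot_pair <- function(plot, stem, width = 9, height = 4, dpi = 150) {
  png_file <- paste0(stem, ".png")
  svg_file <- paste0(stem, ".svg")
  ggplot2::ggsave(png_file, plot, width = width, height = height, dpi = dpi,
                  device = grDevices::png, type = "cairo")
  ggplot2::ggsave(svg_file, plot, width = width, height = height,
                  device = grDevices::svg)
  c(png_file, svg_file)
}

#' Export a structure (and optional reactivities) for VARNA
#'
#' Always writes renderer-independent files: a per-nucleotide colour-map
#' value file (missing positions as -1) and a text file holding the
#' complete VARNA command line for the chosen layout. Rendering itself
#' happens only when the VARNA jar is configured. With `grey_out` and a
#' DMS/CMCT profile, positions not susceptible to the probe are flagged
#' for grey rendering. Without a profile (prediction mode) no colouring is
#' emitted.
#'
#' @param structure An [rna_structure()].
#' @param profile Optional normalized [react_profile()] of matching length.
#' @param layout `"radiate"`, `"circular"` or `"linear"`.
#' @param grey_out Flag non-susceptible nucleotides for grey rendering.
#' @param stem Output path stem.
#' @param varna_jar Optional path to the VARNA jar; when set and `java` is
#'   available, the PNG is rendered.
#' @return Invisible list: `files` written, `cmd` the invocation string.
#' @export
varna_export <- function(structure, profile = NULL,
                         layout = c("radiate", "circular", "linear"),
                         grey_out = FALSE, stem = "varna", varna_jar = NULL) {
  layout <- match.arg(layout)
  n <- structure_length(structure)
  if (!is.null(profile) && nrow(profile) != n) {
    cp_abort(sprintf("profile length %d does not match structure length %d",
                     nrow(profile), n), "reconciliation_error")
  }
  db <- write_dotbracket(structure)
  seq <- if (!is.null(profile) && !anyNA(profile$nt)) {
    profile_sequence(profile)
  } else strrep("N", n)
  files <- character(0)
  algorithm <- c(radiate = "radiate", circular = "circular", linear = "line")[[layout]]
  args <- sprintf(
    '-sequenceDBN "%s" -structureDBN "%s" -algorithm %s -o "%s.png"',
    seq, db, algorithm, stem)

  if (!is.null(profile)) {
    cmap_file <- paste0(stem, ".colormap.txt")
    writeLines(ifelse(profile$measured, sprintf("%.3f", profile$reactivity), "-1"),
               cmap_file)
    files <- c(files, cmap_file)
    args <- paste(args, sprintf('-colorMap "%s"', cmap_file))
    probe <- profile_probe(profile)
    if (grey_out && probe %in% c("DMS", "CMCT")) {
      grey <- profile$position[!profile$nt %in% susceptible_letters(probe)]
      if (length(grey)) {
        args <- paste(args,
                      "-basesStyle1 \"fill=#CCCCCC,outline=#999999\"",
                      sprintf('-applyBasesStyle1on "%s"',
                              paste(grey, collapse = ",")))
      }
    }
  }
  cmd <- paste("java -cp VARNA.jar fr.orsay.lri.varna.applications.VARNAcmd", args)
  cmd_file <- paste0(stem, ".varna-cmd.txt")
  writeLines(cmd, cmd_file)
  files <- c(files, cmd_file)
  if (!is.null(varna_jar) && file.exists(varna_jar) && nzchar(Sys.which("java"))) {
    system(sub("VARNA.jar", varna_jar, cmd, fixed = TRUE))
    files <- c(files, paste0(stem, ".png"))
  }
  invisible(list(files = files, cmd = cmd))
}
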