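test_that("colour mapping is pure, in-ramp, and grey only for missing", {
  vals <- c(0, 0.5, 1, NA)
  c1 <- reactivity_colors(vals, "SHAPE")
  c2 <- reactivity_colors(vals, "SHAPE")
  expect_identical(c1, c2)
  expect_equal(c1[1], "#FFFFCC")  # ramp(0)
  expect_equal(c1[3], "#E31A1C")  # ramp(1)
  expect_equal(c1[4], "#BDBDBD")  # missing grey
  expect_false(c1[4] %in% reactivity_colors(seq(0, 1, 0.01), "SHAPE"))
  # DMS/CMCT default ramps differ and end at their stated colours
  expect_equal(reactivity_colors(1, "DMS"), "#238443")
  expect_equal(reactivity_colors(0, "CMCT"), "#FFFFFF")
  expect_error(reactivity_colors(0.5, "sepia"), class = "chemprobe_config_error")
})

test_that("barplot bins are black/orange/red with left-closed boundaries", {
  expect_equal(reactivity_bin_color(c(0.1, 0.5, 0.9)),
               c("black", "orange", "red"))
  expect_equal(reactivity_bin_color(c(0, 0.3, 0.7, 1)),
               c("black", "orange", "red", "red"))
  expect_equal(reactivity_bin_color(NA), "#BDBDBD")
})

test_that("heatmap and barplot build and save for normal and edge profiles", {
  p <- react_profile(c("A", "C", "G"), c(0, 0.5, 1), normalized = TRUE)
  expect_s3_class(plot_reactivity_heatmap(p), "ggplot")
  expect_s3_class(plot_reactivity_barplot(p), "ggplot")
  expect_error(plot_reactivity_heatmap(react_profile("A", 2)),
               class = "chemprobe_state_error")
  # all-missing profile still renders an (empty) axis
  empty <- react_profile(c("A", "C"), c(NA, NA), normalized = TRUE)
  expect_s3_class(plot_reactivity_barplot(empty), "ggplot")

  dir <- withr::local_tempdir()
  files <- save_plot_pair(plot_reactivity_barplot(p), file.path(dir, "bars"))
  expect_true(all(file.exists(files)))
  expect_match(files, "\\.png$|\\.svg$")
})

test_that("varna export writes colour maps, grey-out flags and prediction mode", {
  dir <- withr::local_tempdir()
  s <- parse_dotbracket("((...))")
  p <- react_profile(c("A", "C", "G", "U", "A", "C", "G"),
                     rep(0.5, 7), normalized = TRUE)
  ex <- varna_export(s, p, stem = file.path(dir, "u"))
  cmap <- readLines(file.path(dir, "u.colormap.txt"))
  expect_equal(cmap, rep("0.500", 7))
  expect_match(ex$cmd, "-algorithm radiate")
  expect_match(ex$cmd, "-colorMap")

  # missing positions appear as -1 in the colour map
  p2 <- react_profile(rep("A", 7), c(0.2, NA, rep(0.8, 5)), normalized = TRUE)
  varna_export(s, p2, stem = file.path(dir, "m"), layout = "circular")
  expect_equal(readLines(file.path(dir, "m.colormap.txt"))[2], "-1")

  # CMCT grey-out flags the non-susceptible A/C positions
  pc <- react_profile(c("A", "C", "G", "U", "A", "C", "G"),
                      rep(0.4, 7), probe = "CMCT", normalized = TRUE)
  exg <- varna_export(s, pc, grey_out = TRUE, stem = file.path(dir, "g"))
  expect_match(exg$cmd, 'applyBasesStyle1on "1,2,5,6"')

  # prediction mode: no profile, no colour map argument
  exp <- varna_export(s, stem = file.path(dir, "p"), layout = "linear")
  expect_false(grepl("-colorMap", exp$cmd))
  expect_match(exp$cmd, "-algorithm line")
  expect_error(varna_export(s, react_profile("A", 0.1, normalized = TRUE)),
               class = "chemprobe_reconciliation_error")
})
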