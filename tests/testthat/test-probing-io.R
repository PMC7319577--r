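test_that("sequence canonicalization folds case, maps T to U, rejects junk", {
  expect_equal(as.character(rna_sequence("acgu")), "ACGU")
  expect_equal(as.character(rna_sequence("ACGT")), "ACGU")
  expect_equal(as.character(rna_sequence(">id some desc\nac\ngu\n")), "ACGU")
  expect_equal(attr(rna_sequence(">rs1\nACGU"), "id"), "rs1")
  err <- expect_error(rna_sequence("ACGX"), class = "chemprobe_invalid_sequence")
  expect_match(conditionMessage(err), "position 4")
  expect_error(rna_sequence("  \n"), class = "chemprobe_invalid_sequence")
})

test_that("QuShape parsing reads seqRNA, flags blank cells missing", {
  txt <- "seqNum\tseqRNA\tareaDiff\n1\tA\t0.1\n2\tC\t0.2\n3\tG\t0.3"
  p <- parse_qushape(txt)
  expect_s3_class(p, "react_profile")
  expect_equal(nrow(p), 3)
  expect_equal(p$nt, c("A", "C", "G"))
  expect_equal(p$reactivity, c(0.1, 0.2, 0.3))
  expect_true(all(p$measured))
  expect_false(is_normalized(p))

  p2 <- parse_qushape("seqNum\tseqRNA\tareaDiff\n1\ta\t0.1\n2\tc\t\n3\tt\t0.3")
  expect_equal(p2$measured, c(TRUE, FALSE, TRUE))
  expect_true(is.na(p2$reactivity[2]))
  expect_equal(p2$nt, c("A", "C", "U"))  # canonicalized

  expect_error(parse_qushape("seqNum\tareaDiff\n1\t0.1"),
               class = "chemprobe_format_error")
  expect_error(parse_qushape("seqNum\tseqRNA\tpeak\n1\tA\t1"),
               class = "chemprobe_format_error")
  expect_error(
    parse_qushape("seqNum\tseqRNA\tareaDiff\n1\tA\t1\n1\tC\t2"),
    class = "chemprobe_format_error")
})

test_that("parse_qushape length always equals the data-row count", {
  for (n in c(1, 5, 37)) {
    prof <- synth_profile(random_structure(n, max(0, n %/% 4)), seed = n,
                          missing_rate = 0.3)
    expect_equal(nrow(parse_qushape(synth_qushape(prof))), n)
  }
})

test_that("reconcile reports per-position mismatches and length differences", {
  p <- parse_qushape("seqNum\tseqRNA\tareaDiff\n1\tA\t1\n2\tC\t2\n3\tG\t3\n4\tA\t4")
  expect_equal(nrow(reconcile(p, "ACGA")), 0)
  rep1 <- reconcile(p, "ACGU")
  expect_equal(rep1$position, 4L)
  expect_equal(rep1$profile_nt, "A")
  expect_equal(rep1$reference_nt, "U")
  rep2 <- reconcile(p, "ACGAUU")
  expect_equal(attr(rep2, "length_diff"), -2)
  expect_error(reconcile(p, "ACGAUU", strict = TRUE),
               class = "chemprobe_reconciliation_error")
  expect_silent(reconcile(p, "ACGA", strict = TRUE))
})

test_that("ROI trimming renumbers from 1 and composes additively", {
  prof <- synth_profile(random_structure(10, 2), seed = 3, missing_rate = 0)
  expect_identical(apply_roi(prof, 0, 0), prof)
  t1 <- apply_roi(prof, 2, 3)
  expect_equal(nrow(t1), 5)
  expect_equal(t1$position, 1:5)
  expect_equal(t1$nt, prof$nt[3:7])
  expect_equal(t1$reactivity, prof$reactivity[3:7])
  # successive trims equal one combined trim
  ab <- apply_roi(apply_roi(prof, 1, 1), 1, 2)
  combined <- apply_roi(prof, 2, 3)
  expect_equal(ab$nt, combined$nt)
  expect_equal(ab$reactivity, combined$reactivity)
  expect_error(apply_roi(apply_roi(prof, 3, 2), 3, 2), class = "chemprobe_empty_roi")
})

test_that("reactivity files use -999 for missing and round-trip exactly", {
  p <- read_reactivities("1 0.5\n2 -999\n3 1.0")
  expect_equal(p$measured, c(TRUE, FALSE, TRUE))
  expect_equal(p$reactivity, c(0.5, NA, 1.0))
  expect_true(is_normalized(p))

  expect_equal(sum(read_reactivities("", length = 4)$measured), 0)
  expect_error(read_reactivities("1 abc"), class = "chemprobe_format_error")
  expect_error(read_reactivities("1 0.5\n1 0.7"), class = "chemprobe_format_error")
  expect_error(read_reactivities("1 0.5 9"), class = "chemprobe_format_error")

  # positions absent from the file are missing
  sparse <- read_reactivities("2 0.25\n5 0.75", length = 6)
  expect_equal(which(sparse$measured), c(2L, 5L))

  prof <- react_profile(c("A", "C", "G"), c(0.5, NA, 1.0), normalized = TRUE)
  expect_equal(write_reactivities(prof), "1 0.500\n2 -999\n3 1.000\n")
  expect_error(write_reactivities(react_profile("A", 1)),
               class = "chemprobe_state_error")

  set.seed(42)
  for (k in 1:5) {
    n <- sample(5:60, 1)
    vals <- round(runif(n), 3)
    miss <- runif(n) < 0.2
    vals[miss] <- NA
    prof <- react_profile(sample(c("A", "C", "G", "U"), n, TRUE), vals,
                          normalized = TRUE)
    back <- read_reactivities(write_reactivities(prof))
    expect_equal(back$reactivity, prof$reactivity)
    expect_equal(back$measured, prof$measured)
  }
})
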