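test_that("dot-bracket parsing handles nesting, pseudoknots and errors", {
  s <- parse_dotbracket("((...))")
  expect_equal(as.data.frame(s)[c("i", "j")],
               data.frame(i = c(1L, 2L), j = c(7L, 6L)))
  pk <- parse_dotbracket("((..[[..))..]]")
  expect_equal(as.data.frame(pk)[c("i", "j")],
               data.frame(i = c(1L, 2L, 5L, 6L), j = c(10L, 9L, 14L, 13L)))
  expect_equal(nrow(parse_dotbracket("....")), 0)
  # letter families parse independently
  lt <- parse_dotbracket("A(a)")
  expect_equal(as.data.frame(lt)$i, c(1L, 2L))
  expect_equal(as.data.frame(lt)$j, c(3L, 4L))

  err <- expect_error(parse_dotbracket("((."), class = "chemprobe_parse_error")
  expect_match(conditionMessage(err), "position 1")
  expect_error(parse_dotbracket("(.))"), class = "chemprobe_parse_error")
  expect_error(parse_dotbracket("(.!)"), class = "chemprobe_parse_error")
  expect_error(parse_dotbracket("(...)", length = 7),
               class = "chemprobe_parse_error")
})

test_that("dot-bracket writing inverts parsing and layers pseudoknots", {
  s <- rna_structure(data.frame(i = c(1, 2), j = c(7, 6)), length = 7)
  expect_equal(write_dotbracket(s), "((...))")
  pk <- rna_structure(data.frame(i = c(1, 2, 5, 6), j = c(10, 9, 14, 13)),
                      length = 14)
  expect_equal(write_dotbracket(pk), "((..[[..))..]]")
  expect_equal(write_dotbracket(rna_structure(data.frame(), length = 4)), "....")
})

test_that("parse/write round trip is the identity on random pseudoknotted pairs", {
  set.seed(101)
  for (k in 1:120) {
    len <- sample(8:60, 1)
    s <- random_structure(len, sample(0:(len %/% 3), 1))
    db <- write_dotbracket(s)
    expect_equal(nchar(db), len)
    back <- parse_dotbracket(db)
    expect_equal(as.data.frame(back)[c("i", "j")], as.data.frame(s)[c("i", "j")])
  }
})

test_that("structure invariants are enforced", {
  expect_error(rna_structure(data.frame(i = 1, j = 1), length = 5),
               class = "chemprobe_invalid_structure")
  expect_error(rna_structure(data.frame(i = c(1, 1), j = c(5, 6)), length = 8),
               class = "chemprobe_invalid_structure")
  expect_error(rna_structure(data.frame(i = 2, j = 9), length = 8),
               class = "chemprobe_invalid_structure")
})

test_that("consensus keeps pairs in at least half the inputs", {
  a <- rna_structure(data.frame(i = c(1, 2), j = c(8, 7)), length = 8)
  b <- rna_structure(data.frame(i = c(1, 3), j = c(8, 6)), length = 8)
  cons <- consensus(list(a, a, b))
  expect_equal(as.data.frame(cons)$i, c(1L, 2L))
  expect_equal(as.data.frame(cons)$j, c(8L, 7L))
  expect_equal(cons$frequency, c(1, 2 / 3))

  # occurring in exactly one of two inputs meets the >= 50% rule
  solo <- consensus(list(a, rna_structure(data.frame(), length = 8)))
  expect_true(all(c(1, 2) %in% as.data.frame(solo)$i))
  expect_equal(unique(solo$frequency), 0.5)

  # unanimity reproduces the structure with frequency 1
  u <- consensus(list(a, a, a, a))
  expect_equal(as.data.frame(u)[c("i", "j")], as.data.frame(a)[c("i", "j")])
  expect_equal(unique(u$frequency), 1)

  expect_error(consensus(list(a)), class = "chemprobe_input_count_error")
  expect_error(consensus(list(a, rna_structure(data.frame(), length = 9))),
               class = "chemprobe_reconciliation_error")
})

test_that("consensus equals the brute-force oracle on random ensembles", {
  set.seed(202)
  for (k in 1:100) {
    len <- sample(10:40, 1)
    m <- sample(2:8, 1)
    ens <- replicate(m, random_structure(len, sample(1:(len %/% 3), 1)),
                     simplify = FALSE)
    got <- as.data.frame(consensus(ens))
    want <- brute_consensus(ens)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[c("i", "j", "frequency")], want)
  }
})

test_that("consensus is permutation invariant and anti-monotone in threshold", {
  set.seed(303)
  ens <- replicate(6, random_structure(25, 5), simplify = FALSE)
  base <- as.data.frame(consensus(ens))
  perm <- as.data.frame(consensus(rev(ens)))
  expect_equal(base, perm)
  lower <- as.data.frame(consensus(ens, threshold = 0.3))
  higher <- as.data.frame(consensus(ens, threshold = 0.8))
  expect_true(all(paste(higher$i, higher$j) %in% paste(lower$i, lower$j)))
  expect_lte(nrow(as.data.frame(consensus(ens, threshold = 0.9))),
             nrow(as.data.frame(consensus(ens, threshold = 0.5))))
})
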