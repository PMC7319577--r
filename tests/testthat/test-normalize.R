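test_that("selection counts follow the ceil(10%)/ceil(20%) rule", {
  expect_equal(selection_counts(100), c(n_selected = 10L, n_excluded = 2L))
  expect_equal(selection_counts(20), c(n_selected = 2L, n_excluded = 1L))
  expect_equal(selection_counts(11), c(n_selected = 2L, n_excluded = 1L))
  err <- expect_error(selection_counts(10), class = "chemprobe_too_few_values")
  expect_match(conditionMessage(err), "11")
})

test_that("normalization factor matches hand-derived worked examples", {
  expect_equal(normalization_factor(1:20), 19)       # select {20,19}, drop {20}
  expect_equal(normalization_factor(1:100), 94.5)    # mean of 91..98
  expect_equal(normalization_factor(sample(1:100)), 94.5)  # order-free
  expect_error(normalization_factor(rep(-1, 50)),
               class = "chemprobe_non_positive_factor")
})

test_that("normalization factor equals the brute-force oracle on random input", {
  set.seed(11)
  for (k in 1:60) {
    n <- sample(11:50, 1)
    vals <- rexp(n, rate = 1 / 5) + runif(n)
    expect_identical(normalization_factor(vals), brute_factor(vals))
  }
})

test_that("normalized profiles are divided then clamped to [0,1]", {
  p <- react_profile(rep("A", 20), 1:20)
  fit <- normalize_profile(p)
  expect_equal(fit$factor, 19)
  expect_equal(fit$profile$reactivity[18], 18 / 19)
  expect_equal(fit$profile$reactivity[19:20], c(1, 1))  # clamped
  expect_true(is_normalized(fit$profile))
  expect_error(normalize_profile(fit$profile), class = "chemprobe_state_error")

  # negatives clamp to 0; missing stays missing
  vals <- c(-2, -0.5, 1:20)
  vals[5] <- NA
  p2 <- react_profile(rep("G", 22), vals)
  out <- normalize_profile(p2)$profile
  expect_equal(out$reactivity[1:2], c(0, 0))
  expect_true(is.na(out$reactivity[5]) && !out$measured[5])
  expect_true(all(out$reactivity[out$measured] >= 0 &
                  out$reactivity[out$measured] <= 1))
  expect_false(any(is.nan(out$reactivity)))
})

test_that("normalization is exactly scale invariant and monotone", {
  set.seed(7)
  for (k in 1:10) {
    n <- sample(15:80, 1)
    vals <- rexp(n, 1 / 3)
    base <- normalize_profile(react_profile(rep("A", n), vals))$profile
    for (c in c(0.5, 3, 1e6)) {
      scaled <- normalize_profile(react_profile(rep("A", n), c * vals))$profile
      expect_equal(scaled$reactivity, base$reactivity, tolerance = 1e-12)
    }
    ord <- order(vals)
    expect_true(all(diff(base$reactivity[ord]) >= 0))
  }
})

test_that("nucleotide-specific mode restricts the divisor but scales all", {
  nt <- rep(c("A", "C", "G", "U"), 5)
  vals <- numeric(20)
  vals[nt %in% c("A", "C")] <- 1:10          # DMS-susceptible carry 1..10
  vals[nt %in% c("G", "U")] <- 1000          # huge signal at G/U
  p <- react_profile(nt, vals, probe = "DMS")
  # only ten susceptible values: below the minimum the ceil rule supports
  expect_error(normalize_profile(p, nucleotide_specific = TRUE),
               class = "chemprobe_too_few_values")
  # with sixteen susceptible values the divisor comes from A/C only
  nt2 <- rep(c("A", "C", "G"), 8)
  vals2 <- numeric(24)
  vals2[nt2 %in% c("A", "C")] <- 1:16
  vals2[nt2 == "G"] <- 1e5
  fit2 <- normalize_profile(react_profile(nt2, vals2, probe = "DMS"),
                            nucleotide_specific = TRUE)
  expect_equal(fit2$factor, brute_factor(1:16))
  expect_true(all(fit2$profile$reactivity[nt2 == "G"] == 1))  # clamped
  expect_match(fit2$subset, "A,C")

  # too few susceptible values errors and names the subset
  small <- react_profile(c(rep("G", 30), "A"), c(1:30, 5), probe = "DMS")
  err <- expect_error(normalize_profile(small, nucleotide_specific = TRUE),
                      class = "chemprobe_too_few_values")
  expect_match(conditionMessage(err), "susceptible")
})

test_that("glance/tidy expose the fit; autoplot returns a ggplot", {
  fit <- normalize_profile(react_profile(rep("U", 100), 1:100))
  g <- glance(fit)
  expect_equal(g$factor, 94.5)
  expect_equal(g$n_divisor, 8L)
  expect_equal(nrow(tidy(fit)), 100)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("replicate averaging uses available replicates only", {
  a <- react_profile(c("A", "C"), c(0.2, NA), normalized = TRUE)
  b <- react_profile(c("A", "C"), c(0.4, 0.6), normalized = TRUE)
  avg <- average_profiles(list(a, b))
  expect_equal(avg$reactivity, c(0.3, 0.6))
  expect_true(all(avg$measured))
  expect_true(is_normalized(avg))
  # symmetric in replicate order; idempotent on identical replicates
  expect_equal(average_profiles(list(b, a))$reactivity, avg$reactivity)
  expect_equal(average_profiles(list(b, b))$reactivity, b$reactivity)
  # missing everywhere stays missing
  c1 <- react_profile(c("A", "C"), c(NA, 0.1), normalized = TRUE)
  c2 <- react_profile(c("A", "C"), c(NA, 0.3), normalized = TRUE)
  expect_equal(average_profiles(list(c1, c2))$measured, c(FALSE, TRUE))
  # guards
  expect_error(average_profiles(list(a, react_profile("A", 0.1, normalized = TRUE))),
               class = "chemprobe_reconciliation_error")
  expect_error(average_profiles(list(a, react_profile(c("A", "C"), c(1, 2)))),
               class = "chemprobe_state_error")
})
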