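#' Counts for the outlier-trimmed normalization rule
#'
#' The normalization protocol selects the 10% most reactive positions and
#' excludes the top 20% of that selection as outliers; the divisor is the
#' mean of the remaining ~8%. Both counts round up (`ceiling`) so the rule
#' stays defined for small inputs; the smallest N for which at least one
#' value survives is 11.
#'
#' @param n Number of measured values entering the statistic.
#' @return Named integer vector `c(n_selected =, n_excluded =)`.
#' @export
selection_counts <- function(n) {
  stopifnot(length(n) == 1, n >= 1)
  n_selected <- as.integer(ceiling(0.10 * n))
  n_excluded <- as.integer(ceiling(0.20 * n_selected))
  if (n_selected - n_excluded < 1) {
    cp_abort(
      sprintf(paste0("too few values (N = %d) for the 10%%-selected/20%%-excluded ",
                     "rule; at least 11 measured values are required"), n),
      "too_few_values", n = n
    )
  }
  c(n_selected = n_selected, n_excluded = n_excluded)
}

#' Normalization divisor for raw reactivities
#'
#' Ranks the values in descending order (stable: ties keep input order),
#' discards the `n_excluded` highest as outliers, and returns the mean of
#' the values ranked `n_excluded + 1` through `n_selected`.
#'
#' @param values Numeric vector of measured raw reactivities.
#' @return The positive divisor.
#' @export
normalization_factor <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) cp_abort("values must be measured (no NA)", "invalid_profile")
  counts <- selection_counts(length(values))
  ord <- order(values, decreasing = TRUE, method = "radix")
  band <- values[ord][(counts[["n_excluded"]] + 1):counts[["n_selected"]]]
  factor <- mean(band)
  if (!is.finite(factor) || factor <= 0) {
    cp_abort(
      sprintf("normalization factor is non-positive (%.4g): top reactivities are not positive",
              factor),
      "non_positive_factor"
    )
  }
  factor
}

#' Normalize a raw reactivity profile
#'
#' Computes the divisor from the measured values -- all of them for SHAPE,
#' or only those at probe-susceptible letters when `nucleotide_specific =
#' TRUE` (A/C for DMS, G/U for CMCT) -- divides every measured value by it,
#' and clamps the results to \[0, 1\]: values above 1 become 1, negatives
#' become 0. Missing positions stay missing. Non-susceptible positions are
#' still divided and clamped so they remain displayable; masking them for
#' engine input is a writer concern (see [varna_export()] `grey_out`).
#'
#' @param profile A raw [react_profile()].
#' @param nucleotide_specific Restrict the divisor to probe-susceptible
#'   nucleotides (only meaningful for DMS/CMCT).
#' @return An object of class `react_norm`: the normalized profile plus the
#'   factor and selection counts. Use [generics::tidy()] for the
#'   per-position table and [generics::glance()] for the one-row summary.
#' @examples
#' p <- react_profile(rep("A", 20), 1:20)
#' fit <- normalize_profile(p)
#' glance(fit)$factor  # 19
#' @export
normalize_profile <- function(profile, nucleotide_specific = FALSE) {
  if (is_normalized(profile)) {
    cp_abort("profile is already normalized", "state_error")
  }
  probe <- profile_probe(profile)
  letters <- susceptible_letters(probe)
  subset_label <- "all measured"
  in_subset <- profile$measured
  if (nucleotide_specific) {
    in_subset <- in_subset & profile$nt %in% letters
    subset_label <- sprintf("susceptible (%s)", paste(letters, collapse = ","))
  }
  values <- profile$reactivity[in_subset]
  rethrow_with_subset <- function(e) {
    cp_abort(sprintf("%s [subset: %s]", conditionMessage(e), subset_label),
             class = sub("^chemprobe_", "", class(e)[[1]]))
  }
  if (length(values) == 0) {
    cp_abort(sprintf("no measured values [subset: %s]", subset_label),
             "too_few_values")
  }
  counts <- tryCatch(selection_counts(length(values)),
                     chemprobe_error = rethrow_with_subset)
  factor <- tryCatch(normalization_factor(values),
                     chemprobe_error = rethrow_with_subset)
  scaled <- pmin(1, pmax(0, profile$reactivity / factor))
  out <- tibble::as_tibble(profile)
  out$reactivity <- ifelse(profile$measured, scaled, NA_real_)
  norm_profile <- new_react_profile(out, probe = probe, normalized = TRUE,
                                    origin = attr(profile, "origin", exact = TRUE))
  structure(
    list(profile = norm_profile, factor = factor,
         n_selected = counts[["n_selected"]], n_excluded = counts[["n_excluded"]],
         n_measured = length(values), subset = subset_label),
    class = "react_norm"
  )
}

#' @export
print.react_norm <- function(x, ...) {
  cat(sprintf(
    "<react_norm> factor = %.4g from %d values (%d selected, %d excluded; %s)\n",
    x$factor, x$n_measured, x$n_selected, x$n_excluded, x$subset))
  print(x$profile)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-position table of a normalization fit
#'
#' @param x A `react_norm` from [normalize_profile()].
#' @param ... Unused.
#' @return The normalized profile as a tibble.
#' @exportS3Method generics::tidy
tidy.react_norm <- function(x, ...) tibble::as_tibble(x$profile)

#' One-row summary of a normalization fit
#'
#' @param x A `react_norm` from [normalize_profile()].
#' @param ... Unused.
#' @return Tibble with the divisor, selection counts and subset used.
#' @exportS3Method generics::glance
glance.react_norm <- function(x, ...) {
  tibble::tibble(factor = x$factor, n_measured = x$n_measured,
                 n_selected = x$n_selected, n_excluded = x$n_excluded,
                 n_divisor = x$n_selected - x$n_excluded, subset = x$subset)
}

#' Average replicate profiles
#'
#' Replicates are normalized before averaging; per position the mean is
#' taken over the replicates where the position was measured, and a
#' position is missing only when it is missing in every replicate. Means of
#' values in \[0, 1\] stay in \[0, 1\], so the result is itself normalized.
#'
#' @param profiles List of two or more normalized [react_profile()]s over
#'   the same sequence.
#' @return The averaged normalized [react_profile()].
#' @export
average_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  ref <- profiles[[1]]
  for (p in profiles) {
    if (!is_normalized(p)) {
      cp_abort("all replicate profiles must be normalized before averaging",
               "state_error")
    }
    if (nrow(p) != nrow(ref) || !identical(p$nt, ref$nt)) {
      cp_abort("replicate profiles disagree in length or sequence",
               "reconciliation_error")
    }
  }
  vals <- vapply(profiles, function(p) p$reactivity, numeric(nrow(ref)))
  vals <- matrix(vals, nrow = nrow(ref))
  mean_val <- rowMeans(vals, na.rm = TRUE)
  measured <- rowSums(!is.na(vals)) > 0
  mean_val[!measured] <- NA_real_
  react_profile(ref$nt, mean_val, measured, probe = profile_probe(ref),
                normalized = TRUE,
                origin = sprintf("mean of %d replicates", length(profiles)))
}
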