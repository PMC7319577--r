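# chemprobe

Normalization, analysis and visualization of low-throughput RNA chemical
probing data (SHAPE, DMS, CMCT) read out by capillary electrophoresis.

Chemical probing reagents modify flexible/unpaired nucleotides; after
QuShape turns chromatograms into per-nucleotide raw reactivities, those
numbers still need normalization, format conversion, structure prediction
and plotting before they mean anything. `chemprobe` does that end-to-end
for single-RNA experiments:

* reads QuShape tab-separated output (`seqRNA` + a reactivity column) and
  pre-normalized reactivity files (`position value`, −999 = unknown), with
  sequence reconciliation and region-of-interest trimming;
* applies the standard outlier-trimmed normalization: select the top 10%
  of reactivities, exclude the top 20% of *those* as outliers, divide
  everything by the mean of the remaining ~8% band, then clamp to [0, 1]
  (negatives → 0, >1 → 1). For DMS/CMCT the divisor can be restricted to
  the susceptible nucleotides (A/C for DMS, G/U for CMCT);
* normalizes replicates independently, then averages per position over
  the replicates with a measured value;
* drives external folding engines per mode (SHAPE: RNAfold + ShapeKnots;
  DMS/CMCT: RNAstructure Fold; prediction mode: eight sequence-only
  methods), skipping cleanly whatever is not installed;
* computes the base-pair consensus: every pair present in ≥ 50% of the
  predictions, with deterministic conflict resolution;
* renders reactivity heatmaps and barplots (bins 0–0.3 black, 0.3–0.7
  orange, 0.7–1 red), exports VARNA colour maps/commands, and writes
  reactivities into the B-factor columns of a PDB file for 3D colouring.

Everything is tibble-first: profiles, base-pair sets, predictions and the
results table are data frames that flow through dplyr pipelines, with
`tidy()`/`glance()` on normalization fits and `autoplot()` on profiles.

## Worked example

Normalize a raw profile of values 1…20 (any arbitrary instrument scale):

```r
library(chemprobe)
fit <- normalize_profile(react_profile(rep("A", 20), 1:20))
glance(fit)
#> # A tibble: 1 × 6
#>   factor n_measured n_selected n_excluded n_divisor subset
#>    <dbl>      <int>      <int>      <int>     <int> <chr>
#> 1     19         20          2          1         1 all measured
```

Two values are selected (10% of 20, rounded up), the single highest is
excluded, so the divisor is the second-largest raw value, 19. Position 18
becomes 18/19 ≈ 0.947; positions 19–20 clamp to 1.

Consensus over three mock predictions:

```r
preds <- list(parse_dotbracket("((....))"), parse_dotbracket("((....))"),
              parse_dotbracket("(..()..)"))
consensus(preds)
#> <rna_structure> consensus: 8 nt, 2 pairs
#> # A tibble: 2 × 3
#>       i     j frequency
#>   <int> <int>     <dbl>
#> 1     1     8     1
#> 2     2     7     0.667
```

The pair (1,8) appears in all three predictions, (2,7) in two of three;
(4,5) appears once (33%) and is dropped by the ≥ 50% rule.

A full SHAPE run from the shell (synthetic QuShape input; RNAfold is
invoked if on PATH, ShapeKnots skipped if absent):

```sh
Rscript inst/cli/chemprobe.R shape --seq seq.txt --qushape rep1.tsv \
    --outdir out --job demo
#> normalization[1]: factor 532.7614 from 28 values (all measured)
#> engine RNAfold-SHAPE: ok
#> engine ShapeKnots: skipped
#> files written:
#>   out/demo.reactivities.txt
#>   out/demo.heatmap.png
#>   ...
```

The output directory contains the normalized reactivities file (−999 at
missing positions), heatmap/barplot as PNG + SVG, VARNA colour-map and
command files for the radiate/circular/linear layouts, the results table
as CSV and tab-delimited text, the all-predictions text file, and the run
log.

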