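---
title: "Analysing RNA chemical probing data with chemprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing RNA chemical probing data with chemprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemprobe)
```

## The problem

Chemical probing interrogates RNA structure in solution: a reagent modifies
nucleotides that are flexible or unpaired, modification sites are read out by
reverse-transcription stops resolved on capillary electrophoresis, and
software such as QuShape converts the chromatograms into per-nucleotide raw
reactivities. Three reagent chemistries are supported here:

* **SHAPE** reagents (NMIA, 1M7) acylate the 2′-hydroxyl of the backbone and
  report flexibility at every nucleotide;
* **DMS** methylates the Watson–Crick face of unpaired adenine (N1) and
  cytosine (N3);
* **CMCT** modifies unpaired uracil (N3) and guanine (N3).

High reactivity therefore marks unpaired or flexible positions, and
protection marks base-paired ones. Downstream folding engines (RNAfold,
ShapeKnots, Fold) accept these reactivities as pseudo-energy restraints, but
only after a strict, reproducible normalization. `chemprobe` implements that
normalization, the surrounding file formats, engine orchestration, a
base-pair consensus over predictions, and visualization — for
low-throughput, single-molecule experiments (not transcriptome-wide
NGS-based probing).

## The normalization model

Raw reactivities sit on an arbitrary instrument scale. The standard
outlier-trimmed ("box-plot") protocol rescales them:

1. select the 10% most reactive positions;
2. exclude the top 20% of that selection as outliers;
3. divide every reactivity by the mean of the surviving ~8% band;
4. clamp: values above 1 become 1, negatives become 0.

Both counts are rounded up (`ceiling`), a choice that keeps the rule defined
for short profiles; the smallest profile it supports is 11 measured values,
and the error raised below that reports this minimum. Ranking ties are
broken by position order (stable sort), so the divisor is deterministic.
The excluded values are the very highest ones, matching the outlier-removal
intent of the protocol.

```{r}
fit <- normalize_profile(react_profile(rep("A", 20), 1:20))
glance(fit)
```

With 20 values, 2 are selected and 1 excluded, so the divisor is the second
largest value (19); positions 19–20 clamp to 1.

Two properties follow and are enforced by the test suite: the output never
leaves \[0, 1\] and never contains NaN; and the result is invariant to any
positive rescaling of the input (the divisor scales with the data). The
invariance is exact in exact arithmetic; in floating point it holds to
round-off (about one ulp), which is how the property test asserts it.

**Nucleotide-specific mode.** For DMS and CMCT the divisor can be computed
from susceptible letters only (A/C for DMS, G/U for CMCT). All positions —
susceptible or not — are still divided and clamped, so the full profile
remains displayable; greying out non-susceptible positions is a rendering
option (`grey_out`), not a data transformation. Whether non-susceptible
positions should instead be masked to −999 in engine input files is exposed
as a writer flag rather than hard-wired, since either behaviour is
defensible.

**Replicates** are normalized first and averaged second, per position over
the replicates in which the position was measured; a position is missing
only if it is missing everywhere. Means of \[0, 1\] values stay in \[0, 1\].

## Missing data conventions

Internally a missing readout is a state (`measured = FALSE`), never a magic
number. Writers substitute the conventional sentinels: −999 in reactivity
files (the dialect RNAfold and ShapeKnots read), −1 in display tables,
VARNA colour maps and PDB B-factor fields. Values in reactivity files carry
3 decimal places; the write→read round trip preserves values (to that
precision) and missing states exactly.

## Structures, pseudoknots and consensus

Dot-bracket strings are parsed with one stack per bracket family — `()`,
`[]`, `{}`, `<>`, then `Aa`, `Bb`, … — so crossing families encode
pseudoknots. Writing is the inverse: pairs are processed in ascending `i`
and placed greedily in the first family where they cross nothing already
placed there. No minimum hairpin-loop size is imposed on user structures;
folding engines enforce their own geometry.

The consensus over a set of equal-length predictions keeps every base pair
present in at least half of them (threshold configurable in (0, 1]; the
boundary is inclusive, so a pair in exactly 5 of 10 predictions is kept).
Because pairs passing the threshold can still share a nucleotide, conflicts
are resolved deterministically: higher occurrence frequency first, then
smaller `(i, j)`. Pseudoknotted and nested pairs are counted identically —
consensus is pure pair-set arithmetic.

```{r}
preds <- list(parse_dotbracket("((....))"), parse_dotbracket("((....))"),
              parse_dotbracket("(..()..)"))
consensus(preds)
```

## Prediction engines

Engines are external programs behind a registry: SHAPE mode drives RNAfold
(reactivity mode) and ShapeKnots; DMS and CMCT modes drive RNAstructure
Fold with the matching option; prediction mode drives the eight
sequence-only methods (RNAfold, Fold, ProbKnot, CentroidFold, CONTRAFold,
IPknot, LinearFold-C, LinearFold-V). All run with their default settings,
including each tool's default pseudo-energy slope/intercept; the conversion
of reactivities to pseudo-energies happens inside the tools and is not
re-implemented. A missing executable yields a *skipped* prediction with a
warning — never a failure — so a partial tool installation still produces
every probing artifact; only structure-dependent outputs are absent when
every engine is skipped. `mock_engine()` provides an in-process stand-in
with scriptable ok/failed/skipped outcomes for testing and examples.

## Visualization and 3D mapping

Heatmaps use probe-specific sequential ramps (SHAPE yellow–orange–red, DMS
yellow–green, CMCT white–red) with alternatives available by name; colour
is a pure function of value and scheme, and missing positions use a grey
that no ramp produces. Barplots bin values at 0.3 and 0.7
(black/orange/red); bins are left-closed, so 0.3 is orange and 0.7 red —
the boundary ownership is a documented choice, not a convention of the
protocol. VARNA exports always write renderer-independent colour-map and
command files (radiate, circular or linear layout); rendering happens only
when a VARNA jar is configured, keeping Java optional.

Reactivities map onto 3D structures by rewriting the temperature-factor
columns (61–66, `%6.2f`) of PDB ATOM/HETATM records for the chosen chain.
Residues are matched to profile positions in author-numbering order with an
explicit user offset (no alignment is attempted); letter mismatches are
reported, and more than 10% of them aborts. Every byte outside the
B-factor columns is preserved, which is why the editing is column-wise on
the fixed-width records rather than routed through a PDB writer. Only
single-model handling is intended; multi-model files trigger a warning.

## The synthetic-data generator

`synth_profile()` emulates what probing assumes about structure: positions
paired in a ground-truth structure draw raw signal from
N(paired mean, sd), unpaired positions from N(unpaired mean, sd), truncated
at zero, scaled by an arbitrary instrument gain, with positions dropped as
missing at a fixed rate. The reference conditions used throughout the
tests are a 30-nt hairpin with paired mean 1, unpaired mean 5 (a 5× contrast),
noise sd 0.5, 5% missing, gain 100 — a clean but realistic
capillary-electrophoresis-like contrast. Under these conditions the mean
normalized reactivity of unpaired positions exceeds that of paired
positions in at least 95 of 100 seeded simulations.

What the generator does **not** emulate: sequence-dependent reagent bias,
correlated noise along the read, signal decay with distance from the
primer, and mis-alignment artifacts from chromatogram processing. Passing
tests on synthetic data therefore validate the arithmetic and the
contracts, not the experimental pipeline upstream of the package.

Test and acceptance problem sizes (200 random profiles up to length 500,
100 consensus ensembles of up to 8 structures of length ≤ 40, 500
round-trip structures, 100 recovery simulations on the 30-nt hairpin) were
chosen to exercise the rules densely while keeping the whole suite fast on
a laptop.

## Degenerate inputs and numerical choices

* Fewer than 11 measured values (in the chosen subset): explicit
  `too_few_values` error naming the subset.
* All candidate reactivities non-positive: `non_positive_factor` error
  rather than a negative divisor.
* Profiles already in \[0, 1\] are still renormalized — there is no fast
  path, so results never depend on hidden state.
* ROI trims that consume the whole sequence, unbalanced brackets, duplicate
  file positions, absent PDB chains and over-long sequences (default cap
  600 nt, overridable) all raise typed conditions.
* Renumbering after ROI trimming restarts at 1 (the 5′ offset is retained
  in the profile's origin label), matching the reactivity-file convention
  that numbering is 1-based and contiguous.

## Known limitations

* One probe per run; integrating complementary probes (e.g. DMS + CMCT)
  into a single prediction is out of scope.
* The engine adapters for RNAstructure-family tools and the other
  sequence-only predictors are exercised against synthetic output in the
  test suite; only RNAfold is routinely available to run for real.
* mmCIF structures and multi-model ensembles are not supported for
  B-factor mapping.
* No alternative normalization schemes (IQR box-plot variants,
  winsorizing): one protocol, applied identically every run, is the point.
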