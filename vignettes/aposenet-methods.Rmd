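---
title: "Methods: super-enhancer calling, receptor-binding integration and the chromatin interaction network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer calling, receptor-binding integration and the chromatin interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aposenet)
```

## Scope and data model

This package re-implements, as tested reusable functions, a
regulatory-genomics analysis of how unliganded estrogen receptor alpha
(apoERα) occupies super-enhancers (SEs) and sustains the expression of
nearby coding and lncRNA genes in hormone-deprived breast-cancer cells.
Everything operates on plain data frames holding 0-based half-open
intervals (the BED convention); GTF input (1-based inclusive) is
converted on read, so a single internal convention prevents off-by-one
drift. Chromosome names are matched by exact string equality — silent
"chr" normalization hides input errors. The TSS is `start` for `+`
genes and `end − 1` for `−` genes (the first transcribed base); the
annotation format does not state this and it is the standard
convention.

Upstream steps that produce the inputs — read alignment, peak calling,
differential-expression model fitting — are out of scope: the pipeline
consumes their outputs (BED, bedGraph, GTF, TSV, BEDPE).

## Super-enhancer calling

Peaks on one chromosome are merged transitively whenever the gap
between them is at most `stitch_distance`; the merged interval spans the
constituents exactly. Defaults follow the published ROSE defaults that
the upstream analysis invokes: 12 500 bp stitching and no TSS-proximal
exclusion (`tss_exclusion_window = 0`, configurable because whether the
original run excluded promoter-proximal peaks is not stated).

Each stitched region is scored by **total** input-subtracted signal,

$$\mathrm{net} = \max(\mathrm{chip} - \mathrm{input},\, 0)
  \quad [\mathrm{CPM \cdot bp}],$$

not per-bp density: wide stitched regions accumulating signal across
many constituents are exactly what super-enhancers are, and a density
score would penalize them. The floor at zero matters because input can
exceed ChIP in noise regions and negative values break the cutoff
geometry below.

With net signals sorted ascending, $s_1 \le \dots \le s_n$, the curve is
the familiar hockey stick. Let $m = (s_n - s_1)/(n - 1)$ be the chord
slope. For each candidate index $i$ consider the line of slope $m$
through $(i, s_i)$ and count the points strictly above it; the tangent
index $i^\*$ maximizes this count — equivalently, it minimizes
$s_i - m\,i$, the intercept of the lowest slope-$m$ line touching the
curve. The threshold is $s_{i^\*}$ and regions with
$\mathrm{net} > s_{i^\*}$ are super-enhancers. Ties are broken toward
the **largest** index, which makes the rule degenerate gracefully: a
perfectly linear or flat curve (every point on the tangent line) yields
threshold $s_n$ and an empty SE set rather than an arbitrary call.
Consequences worth noting, all covered by tests:

* membership is invariant under multiplication of all signals by any
  $c > 0$ (both $m$ and the offsets scale);
* the tangent region itself is never super (the comparison is strict),
  so at most $n - 1$ regions can be called;
* fewer than 2 regions → no cutoff exists and nothing is called.

The SE **center**, the reference point for gene association, is the
floor midpoint of the stitched interval; the upstream description
requires a center without defining one, and the floor midpoint is
deterministic on odd-width intervals.

## Receptor-binding integration

*SE-aERBS selection.* An SE is selected when its stitched interval
overlaps at least one apoERα binding site under half-open semantics (a
shared boundary is not an overlap). Selection is monotone in the site
set.

*Gene association.* A gene associates with a region when
$|\mathrm{TSS} - \mathrm{center}| \le$ `max_distance` (100 kb default,
boundary inclusive). The upstream description measures distance from
the SE center in one place and from the SE region in another; the
center-based rule is adopted everywhere as the single rule (it matches
the results-level description), with edge-based distance available
behind a flag. "First proximal gene TSS" is read as nearest TSS
(distance ties broken by lexicographically smaller gene id); first in
genomic order was the other candidate reading and is not implemented.
Genes with several annotated TSSs are represented by the longest
isoform's TSS.

*DE classification.* `down` iff `adj_p < α` and log2FC < 0, `up`
symmetric, everything else `unchanged` — including log2FC exactly 0, so
the three labels partition the table. α = 0.001 for the silencing
experiment and 0.05 for the estrogen time-course, the thresholds of the
corresponding upstream fits. Records with missing `adj_p` are skipped
with a warning count rather than silently dropped.

*Bias summary.* Per DE class, the fraction of genes with ≥ 1 binding
site within 100 kb of the TSS, as a percentage rounded **half-up** to
one decimal (base R rounds half-to-even, which cannot reproduce printed
percentages such as 485/1376 → 35.2). A two-sided Fisher exact test on
the down/up × bound 2 × 2 table is attached as an explicitly labeled
annotation; the original analysis reports the bias without a test.

*Cross-tabulation.* The silencing × time-course label matrix is
restricted to SE-associated genes; genes measured in only one
experiment are counted in "unmeasured" margins so that cells + margins
always reconstruct the gene universe.

*FPKM.* `count / ((L/1000) · M)` with `L` the longest isoform's length
and `M` the counted fragments in millions; zero or negative `L`/`M` is
an error, not a NaN.

## Chromatin interaction network

Promoter footprints cover −2000/+500 bp around the TSS **in the gene's
transcriptional sense**; on the `−` strand the window mirrors to
`[TSS − 499, TSS + 2001)` in genomic coordinates (length 2500 either
way, clipped at position 0). The "around the TSS" phrasing is
direction-ambiguous; the transcription-oriented reading is standard.
Binding sites are padded by 1 kb per side.

Every footprint overlapping anchor 1 of a ChIA-PET pair is linked to
every footprint overlapping anchor 2 — combinatorial fan-out, since the
data do not resolve which co-located element an anchor ties to.
Self-links are discarded and two footprints under the *same* anchor are
never linked (only anchor 1 ↔ anchor 2 carries interaction evidence).
Node pairs are canonicalized as unordered, which also collapses
reciprocal anchor orderings. Edge weight is the mean over experiments
of the per-experiment summed pair counts joining the two footprints —
the "averaging population" is experiments, and single-experiment input
degenerates to a plain count. Pairs whose anchor touches no footprint
go to an unassigned tally.

Because fan-out can attribute one pair to several node pairs, exact
pair-mass conservation is checked in a **first-match** diagnostic mode:
each anchor maps to at most its maximal-overlap footprint, so assigned
plus unassigned counts equal the input counts exactly. Relatedly, in
the planted-loop recovery property the planted enhancer edge is
required to *attain* the maximal weight incident to its promoter rather
than to be its unique maximum: when a planted SE happens to overlap a
neighboring promoter footprint, fan-out duplicates the identical pair
mass into an equal-weight edge that no weighting scheme could separate.

## What the synthetic generator emulates — and what it does not

All generators derive their streams from one master seed by fixed
offsets, so adding a generator never perturbs another and a fixed seed
reproduces every output file byte for byte. Defaults (all in
`sim_config()`): three chromosomes of 12/10/8 Mb; 500 non-overlapping
genes (2–20 kb, placed one per equal-width bin, Gencode-flavoured
biotype weights); 3 planted SEs of 5 × 800 bp peaks with 1.5 kb gaps
(a 10 kb cluster, comfortably under the stitch distance) centered
15–90 kb from a randomly chosen gene TSS; 50 isolated background peaks
(> 12.5 kb from any other peak); background ChIP density 1 CPM, planted
density `se_signal_ratio` × background (default 5); uniform input at
0.1 CPM; two-thirds of planted SEs receive 1–3 binding sites; genes
within 100 kb of a bound SE center are down-regulated with probability
0.75 versus 0.4 background (the remaining mass split equally between up
and unchanged); labels are realized directly as (log2FC, adjusted-p)
pairs with the distributional shape of a differential-expression fit —
the fits themselves are upstream and out of scope; 5 ChIA-PET pairs per
planted loop anchored at the SE's first binding site and the target
promoter, plus 5 uniform noise pairs (≈ one-third noise), counts
1 + Poisson(1).

Two idealizations deserve emphasis. First, background peaks share one
width and one density, so the background rank curve is **flat** and the
tangent cutoff has no spurious elbow; real H3K27ac landscapes have
heavy-tailed background signal, on which any elbow rule calls some
top-quantile background regions. Passing the recovery suites therefore
demonstrates the geometry of the caller, not robustness to realistic
background dispersion. Second, at `se_signal_ratio = 1` a planted
cluster loses its enrichment but keeps its structural advantage — five
constituent peaks still out-sum one background peak under total-signal
ranking, so ratio 1 is *not* a clean null; the clean null is
`n_planted_se = 0`, which the tests use for the false-positive check.
The generator also makes no attempt at sequence content, read-level
noise, replicate structure or copy-number artifacts.

## Problem sizes and numerical choices

The test and acceptance suites run 20-seed replicates of the default
configuration (500 genes, 65 peaks, 15 pairs per landscape), 200-instance
oracle comparisons for stitching (n ≤ 40 per instance, against a
quadratic transitive-merge oracle) and the tangent cutoff (n ≤ 200,
against exhaustive candidate enumeration) — sizes chosen so the whole
suite completes in about a minute while the oracles stay brute-force
honest. Percentages are reproduced from the study's printed integer
counts exactly, so those checks carry no tolerance at all; stochastic
recovery checks use the thresholds stated with each property (mean
Jaccard ≥ 0.9; binomial 3-SE coverage in ≥ 19/20 seeds; top-edge
identity and null emptiness in ≥ 18/20).

Numerical conventions collected in one place: half-up rounding for all
reported percentages; strict `>` against the SE threshold; largest-index
tie-break at the tangent; floor midpoints for centers; inclusive ≤ at
the 100 kb association boundary; empty DE classes report NA rather than
0; empty inputs degrade to empty outputs except where the operation is
undefined (cutoff on < 2 regions, FPKM with non-positive length or
library size), which raise errors.

## Known limitations

* The dataset-level counts of the original study (total SEs, SE-aERBS,
  associated genes) depend on specific accessions, aligners and peak
  callers and are not reproducible from the package's inputs; the
  pipeline reproduces the *rules* and the printed arithmetic summaries,
  and recovers planted truth on synthetic data.
* The tangent cutoff, like any elbow heuristic, is scale-free but
  shape-sensitive: heavy-tailed background changes what it calls, and
  no uncertainty is attached to the threshold.
* Edge weights average over experiments without variance; one
  experiment yields weights that are raw counts.
* The Fisher test annotation treats genes as independent, which
  clustered regulation violates; it is a descriptive annotation, not an
  inferential claim of the pipeline.
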