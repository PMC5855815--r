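# aposenet

Regulatory-genomics pipeline for studying how unliganded (hormone-free)
estrogen receptor alpha (apoERα) engages super-enhancers to sustain gene
expression in breast-cancer cells. Starting from H3K27ac ChIP-seq peaks
and signal tracks, ERα binding sites mapped in hormone-deprived cells
(aERBS), gene models, differential-expression tables and ChIA-PET anchor
pairs, the package

1. **calls super-enhancers** (ROSE-style): peaks within 12.5 kb are
   stitched; each stitched region is ranked by input-subtracted total
   signal; the super-enhancer threshold is the tangent-point of the
   ranked signal curve;
2. **integrates them with receptor binding**: SEs overlapping ≥ 1 aERBS
   ("SE-aERBS") are associated with gene TSSs within 100 kb of the SE
   center, DE tables are classified at per-experiment thresholds, and the
   down-regulation bias of receptor-bound genes is quantified;
3. **builds the chromatin interaction network** from ChIA-PET pairs:
   promoter footprints (−2 kb/+500 bp around the TSS, strand-oriented)
   and 1 kb-padded binding sites become nodes; anchors map pairs onto
   node pairs; edge weight is the mean per-experiment sum of pair counts.

A seeded synthetic-data generator plants super-enhancers, binding sites,
expression biases and chromatin loops with known truth, so the whole
pipeline is testable end-to-end without any external download. It is
aimed at computational biologists who want a transparent, fully tested
re-implementation of this analysis rather than a black-box script
collection.

## The model in brief

Super-enhancer calling. Peaks on one chromosome are merged transitively
whenever their gap ≤ `stitch_distance` (default 12 500 bp). For each
stitched region the ranking signal is

```
net = max(chip − input, 0)          (CPM · bp, total signal over the region)
```

Sorting `net` ascending gives the classic hockey-stick curve
`s_1 ≤ … ≤ s_n`. With chord slope `m = (s_n − s_1)/(n − 1)`, the cutoff
is `s_i*` where `i* = argmax_i #{j : s_j > s_i + m(j − i)}` (ties → the
largest `i`, so flat or linear curves call nothing); regions with
`net > s_i*` are super-enhancers. Membership is invariant under positive
scaling of the signals, and the tangent region itself is never called.

Association and bias. A gene associates with an SE when
`|TSS − SE center| ≤ 100 kb` (inclusive; center = floor midpoint).
DE classes are `down`/`up`/`unchanged` at `adj_p < α` and the sign of
log2FC (α = 0.001 for receptor silencing, 0.05 for the estrogen
time-course). The binding-bias table reports, per class, the percentage
of genes with a binding site within 100 kb of the TSS, rounded half-up
to one decimal — from the study's printed counts (485/1376 bound down,
300/1110 bound up) this gives 35.2% vs 27.0%.

Network. Each node footprint overlapping anchor 1 of a pair is linked to
each footprint overlapping anchor 2 (self-links and same-anchor
co-bindings excluded); per experiment the pair counts joining a node
pair are summed, and the edge weight is the mean of those sums across
experiments. A first-match diagnostic mode assigns each anchor to its
maximal-overlap footprint so that pair mass is conserved exactly.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data (each is a thin driver over exported functions; outputs land in
`results/`):

```sh
Rscript analysis/01_simulate.R    # seeded inputs + planted truth
Rscript analysis/02_call_se.R     # super-enhancer calling
Rscript analysis/03_integrate.R   # SE-aERBS, associations, bias, crosstab
Rscript analysis/04_network.R     # ChIA-PET network
Rscript analysis/05_report.R      # one-call pipeline + determinism check
```

`02_call_se.R` prints (seed 1):

```
53 stitched regions; 3 called super-enhancers
top regions by net signal:
 chrom   start     end n_constituents net_signal rank is_super
  chr1 3059595 3069595              5      19000    1     TRUE
  chr1 4255611 4265611              5      19000    2     TRUE
  chr3 5708995 5718995              5      19000    3     TRUE
  chr1  129363  130163              1        720    4    FALSE
per-planted-SE best Jaccard vs called SEs: 1.000 1.000 1.000
```

All three planted clusters are recovered exactly: each contributes
5 × 800 bp of ChIP at 5× background density, i.e. net ≈ 19 000 CPM·bp,
against ≈ 720 for an isolated background peak, and the tangent cutoff
lands on the flat background shelf. `03_integrate.R` then reports the
2 bound SEs as SE-aERBS, 7 associated DE genes of which 85.7% are
down-regulated (the generator plants P(down | bound SE within 100 kb) =
0.75 against 0.4 background), and `04_network.R` finds the two planted
promoter–enhancer edges as the heaviest in the network (weights 13 and
10 — summed loop counts — versus nothing above 4 elsewhere).

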