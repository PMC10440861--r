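---
title: "Classifying large mutational events into channel matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying large mutational events into channel matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNSVMatrix)
```

## Motivation

Mutational-signature analysis factorizes a channel-by-sample count matrix
into signatures and per-sample activities. For small events (single-base
substitutions, indels) the channel schemas are long established; for *large*
events — copy-number variants (CNVs) and structural variants (SVs) — two
schemas are in wide use: a 48-channel classification of allele-specific
copy-number segments and a 32-channel classification of rearrangements.
CNSVMatrix turns caller output (segmentation tables, BEDPE) into those
matrices and the per-sample profile plots that go with them.

## The 48-channel copy-number schema

Each segment carries a major-allele count $A$ and a minor-allele count $B$
($A \ge B \ge 0$), with total copy number $\mathrm{TCN} = A + B$. Segments
fall into three heterozygosity states:

* **het** — $A > 0,\ B > 0$;
* **LOH** — $A > 0,\ B = 0$ (loss of heterozygosity; $\mathrm{TCN}=2$ is
  copy-neutral LOH);
* **homdel** — $A = B = 0$ (homozygous deletion).

TCN is classed into $\{0\}, \{1\}, \{2\}, \{3,4\}, \{5\text{–}8\},
\{\ge 9\}$; the 3–4 and 5–8 classes absorb one and two rounds of
whole-genome doubling, and $\ge 9$ captures high-level amplification such as
ecDNA. Segment length (bp, `end - start + 1` under 1-based inclusive
coordinates) is binned into 0–100 kb, 100 kb–1 Mb, 1 Mb–10 Mb, 10 Mb–40 Mb,
\>40 Mb for het/LOH segments and 0–100 kb, 100 kb–1 Mb, \>1 Mb for
homozygous deletions. The admissible combinations are 20 het + 25 LOH + 3
homdel = 48 mutually exclusive channels.

Two conventions are deliberately fixed here because the schema's prose does
not pin them down:

* **Bin edges are left-open, right-closed**: a segment of exactly 100,000 bp
  is `0-100kb`; 100,001 bp is `100kb-1Mb`. One consistent rule removes all
  edge ambiguity and is enumerated in the tests.
* **Channel order** (homdel block, then LOH, then het, each by TCN class
  then size) is fixed by `cnv48_channels()` so that matrices from different
  runs are always row-compatible.

Fractional allele copy numbers (PURPLE, Battenberg fits) are rounded half
away from zero by `normalize_alleles()`; rows with a missing minor-allele
count are skipped with a warning rather than imputed, since the
heterozygosity state is undefined without it. Diploid `2:het` segments are
counted — the schema includes those channels explicitly. Chromosomes outside
1–22/X/Y are skipped with a warning (the schema is a human-genome one).

```{r}
classify_cnv_segment(2, 0, 1, 6e7)   # copy-neutral LOH, > 40 Mb
classify_cnv_segment(9, 3, 1, 2e6)   # high-level amplification
```

Six caller dialects (ASCAT, ABSOLUTE, Sequenza, FACETS, Battenberg, PURPLE)
plus a generic format are supported by `read_segmentation()`; the column
mappings are in its help page. FACETS reports total and minor copy number,
so the major allele is reconstructed as `tcn.em - lcn.em`; for Battenberg
the clonal state columns (`nMaj1_A`/`nMin1_A`) are used, one state per
segment. All tables are read as 1-based inclusive coordinates.

## The 32-channel structural-variant schema

Each SV contributes two single-base breakpoints. The class is taken from a
`svclass` column when present, otherwise inferred from strand orientation:
mates on different chromosomes are translocations; on the same chromosome
`+/+` is a deletion, `-/-` a tandem duplication, `+/-` or `-/+` an
inversion. Deletions, tandem duplications and inversions are size-binned
(0–10 kb, 10–100 kb, 100 kb–1 Mb, 1 Mb–10 Mb, \>10 Mb, again left-open
right-closed); translocations are not, because a balanced or unbalanced
translocation has no single size. Crossed with the clustered /
non-clustered annotation this gives $2 \times (3 \times 5 + 1) = 32$
channels.

### Clustered rearrangements

Chromothripsis, chromoplexy and rearrangement hotspots produce breakpoints
far closer together than chance. The annotation works per sample:

1. Both mates of every SV are pooled per chromosome and sorted; each
   breakpoint's inter-mutational distance (IMD) is the distance to its
   predecessor. The first breakpoint takes the distance to its successor so
   that a cluster at a chromosome edge is not truncated; a chromosome with a
   single breakpoint contributes no IMD.
2. Each chromosome's $\log_{10}(\mathrm{IMD}+1)$ series is segmented by an
   exact Potts filter: `pcf_segment()` minimizes
   $\sum_s \sum_{i \in s}(x_i - \bar x_s)^2 + \gamma k$ over all
   partitions into $k$ contiguous segments, by dynamic programming over cut
   points in $O(n^2)$, ties broken toward fewer segments. The exactness
   matters: it makes the segmentation deterministic and lets the test suite
   verify it against exhaustive enumeration of all $2^{n-1}$ partitions.
3. A segment is **clustered** when its mean raw IMD is at most the sample
   mean IMD (over all chromosomes jointly) divided by 10 *and* it contains
   at least 10 breakpoints. An SV is clustered when either of its mates lies
   in a clustered segment — breakpoints, not events, are what cluster
   spatially.

The tenfold rule is read as *tenfold shorter than expected*
(segment mean $\le$ sample mean / 10). The looser literal alternative
("less than 10 times the mean") would mark almost every segment clustered
and would contradict the archetypal all-non-clustered chromosome the schema
is illustrated with, so it is not used.

Tunable parameters, all exposed in `build_sv_matrix()` and on the command
line:

| parameter | default | meaning |
|---|---|---|
| `gamma` | 25 | Potts penalty per segment, on the $\log_{10}$ IMD scale. Larger values merge segments; 25 keeps kilobase-scale clusters separable from megabase background on typical whole-genome breakpoint densities. |
| `cluster_factor` | 10 | a segment must beat the sample mean IMD by this factor |
| `min_cluster_bp` | 10 | minimum breakpoints per clustered segment |

The published formulation of the original Potts-filter procedure does not
print a penalty value or transform; $\gamma = 25$ on the
$\log_{10}(\mathrm{IMD}+1)$ scale (the same scale rainfall plots use) is
this package's documented default, and both the factor and the minimum are
flags so alternative conventions can be reproduced.

Because the clustered test compares a segment mean against the sample mean,
the flags are invariant under rescaling all coordinates by a positive
constant; the property suite checks this at 3×.

```{r}
fx  <- generate_sv_fixture("chromothripsis", n_events = 16, seed = 2,
                           dir = tempdir())
rec <- read_bedpe(fx$file)
table(annotate_clustered(rec))
```

## Matrices, files, and plots

`build_cnv_matrix()` / `build_sv_matrix()` return a `channel_matrix`: an
integer matrix with the canonical channels as rows and samples as columns;
column sums equal per-sample event counts and every channel row is present
even when zero. `write_matrix()` / `read_matrix()` use the standard
mutational-matrix TSV dialect (first column `MutationType`); reading
re-sorts rows to canonical order and rejects unknown labels.

Rendering is separated from data assembly: `profile_data()` returns the
exact bar heights, groupings and colors that `plot_profile()` draws, so
tests assert numbers, not pixels. `rainfall_data()` plays the same role for
`plot_rainfall()`. The palette (one color per SV type, one per
heterozygosity state) is a fixed package choice; the schema itself does not
prescribe colors.

## The synthetic-data generator

`generate_cnv_fixture()` and `generate_sv_fixture()` produce seeded,
byte-reproducible input files together with the intended channel of every
record, so the whole pipeline is testable without any external data.

CNV scenarios draw channels from fixed mixtures emulating archetypal tumor
profiles — `focal_amp` (60% high-TCN het channels at sizes up to 10 Mb, the
ecDNA/focal-amplification pattern), `loh_heavy` (70% TCN = 1 LOH),
`wgd` (70% TCN 3–4 at \>10 Mb), `mixed` (uniform) — then realize each
channel as a concrete non-overlapping segment on chromosomes 1–22 using real
GRCh38 chromosome lengths. The 60/40 focal-amplification split is fixed;
the other mixture weights are package choices picked so the intended
pattern clearly dominates while every channel stays reachable.

SV scenarios are built to make the clustering ground truth *provable from
the geometry*, not merely likely: `chromothripsis` places six
intra-chromosomal events whose 12 breakpoints sit 1 kb apart inside one
window (thousands of times tighter than the ≥5 Mb background spacing, so
the tenfold inequality holds with a wide margin), while `dispersed` caps
events at four per chromosome so no chromosome can reach the ten-breakpoint
minimum regardless of spacing. Classification of a generated file therefore
reproduces the recorded ground truth exactly, and the test suite asserts
that identity across scenarios and seeds.

What the generator does *not* emulate: caller noise (subclonal fractions,
fractional copy numbers, segmentation artifacts), overlapping or adjacent
segments needing merging, breakpoint-mechanism realism, and borderline
clustering geometries near the threshold. Passing the end-to-end tests
therefore demonstrates correctness of the classification and clustering
logic under unambiguous inputs, not robustness to noisy real-world calls —
the reader-level validation rules (skip-with-warning, fatal on missing
columns) are tested separately with hand-built malformed files.

## Numerical and scale choices

* The PCF dynamic program is exact, $O(n^2)$ per chromosome; breakpoint
  counts per chromosome in real samples (tens to a few thousand) keep this
  inexpensive. Objective ties are resolved toward fewer segments with an
  absolute tolerance of $10^{-12}$.
* Test problem sizes: the exhaustive-PCF cross-check runs 200 random series
  of length ≤ 12 (4,096 partitions at most, small enough to enumerate
  honestly); end-to-end fixture recovery runs every scenario at 20 events
  across 20 seeds. These sizes exercise every code path while keeping the
  default suite fast.
* Coincident breakpoints give IMD 0, which the $\log_{10}(x+1)$ transform
  handles without special-casing.
* `half away from zero` rounding (not banker's rounding) is used for allele
  counts so that x.5 states round the same way regardless of parity.

## Limitations

* Human chromosomes 1–22/X/Y only; other contigs are skipped with a warning.
* One state per segment: subclonal copy-number decomposition is out of
  scope, and Battenberg subclonal columns are ignored in favor of the
  clonal state.
* The clustered flag is a per-event annotation; identifying complex-event
  classes (chromothripsis vs chromoplexy) is downstream of this package.
* Translocation balance is not assessed; translocations are one channel per
  clustered status by construction.
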