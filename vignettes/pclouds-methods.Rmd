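---
title: "Oligo-cloud repeat annotation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligo-cloud repeat annotation: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pclouds` annotates repetitive sequence without a repeat library. The
underlying observation is statistical: in a genome of `N` positions a random
oligonucleotide of length `l` is expected `N/4^l` times, so for `l` chosen
such that `N/4^l < 1` (16 for mammalian-sized genomes — see
`recommended_oligo_length()`), any oligo observed many times almost surely
marks repeated sequence. Because repeat copies diverge by substitution, the
signal is not a single high-copy word but a *cloud* of similar words:
a high-copy core surrounded by lower-copy variants one to three
substitutions away. Annotation then reduces to finding regions dense in
cloud members.

The pipeline is: count k-mers (`count_oligos()`), cluster them into clouds
(`build_clouds()`, or `build_esp_clouds()` from a family library),
demarcate member-dense regions (`annotate_repeats()`), and calibrate the
result against a repeat-free null genome
(`simulate_null_genome()`, `estimate_fp_table()`, `assign_posteriors()`).

Assumptions worth keeping in mind:

* Divergence within a repeat family is substitution-like; the sequence space
  searched has no indels. An indel shifts the frame of every overlapping
  k-mer, so indel-riddled families fragment into several clouds and are
  detected piecewise.
* Copy number does the work. A two-copy repeat is indistinguishable from
  background at the default cutoffs, by design.
* The null model for false positives is first-order Markov structure at the
  1-Mbp scale; genuine non-repetitive higher-order structure (e.g. coding
  bias) is charged to the repeat signal, which is why calibration is
  reported as a probability rather than silently subtracted.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 16 | nt | word length; smallest `l` with `N/4^l < 1` |
| `lower` | 2 | copies | minimum count to join a cloud |
| `core` | 10 | copies | minimum count to seed a cloud |
| `ext1/ext2/ext3` | 20/200/2000 | copies | seed count enabling radius 1/2/3 |
| `window` | 10 | oligo starts | demarcation window |
| `min_frac` | 0.8 | fraction | member density for a dense window |
| `window_bp` | 1e6 | bp | null-simulation matching window |
| `density` | 0.10 | fraction | repeat share of benchmark genomes |

The (2, 10, 20, 200, 2000) cutoff set is the conservative whole-genome
choice for mammalian-scale scans; diverged, lower-copy families warrant
laxer settings (the packaged example for an ancient SINE-like family is
(1, 2, 4, 40, 40)). With the defaults, a window is dense at
`ceiling(0.8 * 10) = 8` of 10 members, and the shortest possible annotation
is `window + k - 1 = 25` nt. (Descriptions of this class of annotator
sometimes quote a 24-bp minimum; the geometry here yields exactly 25 and we
treat 24 as approximate.)

## Numerical and algorithmic choices

**Cloud construction is deterministic.** Seeds are processed in
non-increasing count order with lexicographic tie-break; when an oligo is
reachable from two seeds, the first (higher-count) seed keeps it. The
cloud's radius is set by the seed's own count: since growth only admits
oligos at or below the seed's count, the seed is the cloud's most frequent
member, which is what the extension cutoffs are defined against. The
alternative — gating each expansion step on the intermediate member's own
count — is defensible but less reproducible (result depends on traversal
order); we pin the seed-count reading and test it against an exhaustive
brute-force constructor at k = 5.

**Strand handling.** Counting is forward-strand as written, which keeps
count semantics simple; membership lookup at annotation time queries the
oligo *and* its reverse complement, so annotation is strand-symmetric (a
tested invariant: annotating a reverse-complemented record mirrors the
coordinates).

**Non-ACGT symbols.** Any window containing one is skipped — never masked
to a wildcard — and demarcation windows are evaluated only within maximal
runs of valid positions at least `window` long. The practical effect is
that annotation never crosses an assembly gap.

**False-positive table.** FP rates are recorded per exact region length as
a count ratio, `min(1, n_sim(L) * (real_bp/sim_bp) / n_real(L))`, not fitted
parametrically. Lookups for unlisted lengths fall back to the nearest
smaller listed length (FP rates fall with length, so this errs
conservative), and below the table to the overall mean rate. An optional
isotonic, non-increasing-in-length smoothing (`monotone = TRUE`) is
available for sparse length tails but off by default, keeping the raw
estimate primary. Whether the underlying rate "per length" should be a
count ratio or a bp ratio is ambiguous; the count ratio is pinned (the bp
ratio differs only by a factor of L and is recoverable).

**Sensitivity interpolation.** `interpolate_sensitivity()` uses a natural
cubic spline through the measured (size, sensitivity) knots, clamped to
[0, 1], with constant extrapolation beyond the measured range; two knots
degenerate to the connecting line, one knot to a constant with a warning.
Detection in `measure_sensitivity()` is any-overlap (≥ 1 bp) — the most
literal reading of a fragment being "identified" — with an optional
minimum-overlap fraction for stricter analyses. The positional curve is a
trailing running average over 10 consecutive start offsets.
`predict_missed_bp()` refuses to divide by zero sensitivity: such sizes are
excluded and reported.

**BED output.** Coordinates are 0-based half-open everywhere internally and
in BED; scores are `floor(1000 * posterior + 0.5)` (round half up) so files
are byte-stable across platforms.

**Seeds.** Every randomized stage takes an explicit seed, records it in the
run's provenance block, and reproduces byte-identical output from it.

## What the synthetic generator emulates — and what it does not

`plant_genome()` implements a master-element model: each family is a random
master sequence whose copies are mutated i.i.d. per site at a stated
expected divergence (substitutions uniform over the three alternatives;
transition bias optional), optionally truncated, planted on either strand
at uniform non-overlapping positions in first-order Markov background.
This captures the features the method actually keys on — copy number,
divergence, fragmentation, strand — and the truth tables it emits make
recovery measurable exactly.

It does **not** emulate: indel mutation, nested insertions, segmental
duplication, GC/isochore heterogeneity of real backgrounds, satellite
tandem structure, or the skewed age mixture of a real repeat landscape.
Passing the planted-recovery tests therefore shows the machinery is correct
under the stated model, not that any particular sensitivity carries over to
a real genome.

Default study conditions used by the test-suite fixtures and the acceptance
script: a 2-Mbp genome carrying 500 full-length copies of a 300-bp master
at 10% divergence for de novo recovery (and a matched no-family background
for false-positive control); a 200-copy, 15%-divergence family for the
fragment benchmark with the size ladder 30/50/80/100/150/200 bp at 10%
density, 150 independently mutated fragments per size and replicate. These
sizes keep every end-to-end run in the minutes range on one CPU while
leaving enough events for the statistical checks to have power.

Two empirical behaviors of the defaults at these conditions, both
recomputed by `scripts/acceptance.R`, are worth recording. First, at 10%
divergence the conservative cutoffs recover roughly 70–72% of planted bp,
not more: exact master 16-mers occur ~45 times per strand, below `ext2`,
so clouds stop at radius 1, and the 8-of-10 window covers about 72% of copy
length at the resulting member density. Deeper recovery of such diverged
families is exactly what the laxer element-specific settings are for.
Second, the matched null background annotates essentially 0% — the
high-copy signal simply does not arise in 2 Mbp of first-order Markov
sequence — so desk-scale false-positive tables are typically all-zero and
posteriors all 1; length-dependent FP structure only becomes visible at
much larger simulated scales.

## Known limitations

* Desk scale by design: the count table lives in memory (sparse hashing,
  ~tens of bp per distinct oligo). Whole-mammalian-genome runs need the
  same algorithm behind an external counter, which the interfaces do not
  preclude but this build does not provide.
* No indel model anywhere (clouds, benchmark, generator).
* ESP mode assigns family labels only through the family the clouds were
  built from; de novo regions carry no classification.
* The posterior is length-conditional only; it ignores composition, so
  regions in unusual isochores inherit the genome-average rate for their
  length.
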