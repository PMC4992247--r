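---
title: "Methods: de novo repeat landscape annotation with repeatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo repeat landscape annotation with repeatscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

## Scope and model

Avian genome models such as the ~1.05-Gbp chicken assembly carry far more
repeated DNA than library-based annotation (RepeatMasker against a curated
consensus library) reports, because old, diverged and fragmented copies
fall below library-matching thresholds. `repeatscape` implements the
*post-processing* layer of a de novo annotation strategy built around five
successive stages: an overall repeat estimate, SSR (simple sequence
repeat) detection and classification, TE (transposable element) annotation
finishing, dark-matter (DM) mining with conserved genomic copies as
probes, and the merge of an external CNV track. The heavy de novo
consensus builders (TRF, REPET-like pipelines, whole-genome repeat
estimators) are treated as external interface points: this package
consumes their file outputs, or synthetic stand-ins, and does everything
after that.

The package is organised around a small number of ideas:

* **A TE model** is a repeat "species": one main consensus plus all
  consensuses detected as variants. Annotations produced by any consensus
  of the model belong to that model, which is why defragmentation (stack
  resolution, juxtaposition merging, long-join counting) operates
  per-model.
* **The SSR taxonomy** partitions tandem arrays by repeat-unit size:
  simple repeats (1-bp unit, sub-typed polyA for A/T and polyC for C/G),
  microsatellites (2–10 bp), minisatellites (11–60 bp), and for units
  above 60 bp large tandem repeats (2–50 units) versus satellite DNAs
  (>50 units). Arrays of the three small classes are retained only with
  at least 50 repeat units.
* **Dark matter** is recovered by using the annotated copies that are
  strictly longer than 500 bp and at least 80 % identical to their
  consensus as probes for a new scan of the genome, then subtracting
  everything already annotated.
* **Permutation statistics** ask whether an element class is over- or
  under-represented on a chromosome (copies distributed over the
  *reduced genome* — chromosome sizes minus the class's own coverage) and
  where 50-kbp windows are TE hotspots.

## Coordinates and containers

All coordinates are 1-based inclusive, the native convention of GFF3 and
of `IRanges`/`GenomicRanges`, on which the package is built; BED files
are converted to and from 0-based half-open form only at the I/O
boundary (`read_n_index_bed()`, `write_n_index_bed()`). An *annotation
set* is a `GRanges` whose `seqinfo` registers every chromosome length;
coverage denominators are always full registered lengths, N bases
included (an N-excluding denominator is available through the `exclude`
argument of `coverage_fraction()`). Strand is ignored by all set
operations and preserved on surviving features.

## N-gap strip and restore

Some scanning tools mishandle assembly gaps (one treats N-stretches as
A-stretches, generating massive false k-mer families). `strip_n()`
removes every maximal N-run and records it in an `n_index`;
`restore_interval()`/`restore_annotations()` lift stripped-coordinate
results back. An annotation spanning a removed gap is **split** into
parts sharing an identifier rather than extended across the gap — the
gap bases were never scored by the wrapped tool, so bridging them would
fabricate signal. Lower-case and mixed-case N are treated identically;
soft-masked non-N bases pass through verbatim. The mapping is a
per-position bijection on non-N bases, which the test-suite checks
exhaustively on random sequences.

## SSR typing

`parse_trf_dat()` reads the Tandem Repeats Finder `.dat` dialect
(`Sequence:` headers, 15-field records; the recommended invocation
parameters Match,Mismatch,Delta,PM,PI,Minscore,MaxPeriod =
2,5,7,80,10,25,2000 are carried in `pipeline_config()`).
`classify_ssr()` applies the taxonomy above. Decisions worth stating
explicitly:

* Fractional TRF copy numbers are compared directly with the thresholds:
  `>= 50` units retains a small-unit array, and `> 50` units promotes a
  large-unit array to satellite. The retention inequality is exposed as
  `min_units_small` so a strict variant can be configured.
* Sub-typing of 1-bp units uses the consensus unit only (A/T → polyA,
  C/G → polyC).
* Overlapping detections are all retained and classified independently;
  de-duplication belongs to the interval algebra stage, mirroring a
  workflow in which raw detections are loaded into a database before
  selection.

`find_exact_tandems()` is a brute-force detector of perfect tandem runs
(leftmost-anchored, smallest primitive unit). It is *not* a TRF
replacement for imperfect arrays: it exists so planted, mutation-free
arrays have an independent oracle, and so `.dat` fixtures can be
generated (`write_trf_dat()`) without shipping binary data.

## Interval algebra and defragmentation

`resolve_stacks()` keeps one representative per stack of mutually
overlapping same-model features: highest identity to consensus first,
then highest consensus coverage, then longer interval, then
lexicographic consensus name. The first two criteria are the published
selection rule; the two tie-breaks are this package's own deterministic
choice, since the original tool's tie behaviour is not documented.
`merge_juxtaposed()` fuses same-model features separated by at most
`max_gap` bp (default 0, bookended only — the original gap value is
unpublished, so the conservative choice is the default and the value is
configurable). `long_join_copies()` counts two same-model fragments as
one copy when the gap between them is entirely covered by features of
other models (the nested insertion) and no larger than
`max_nested_span`; intervals stay split, only copy identity changes.
`filter_min_length()` applies the 20-bp minimum copy size.

Base-level set operations (`intersect_annotations()`,
`subtract_annotations()`, `union_coverage()`, `venn_coverage()`) stand
on `GenomicRanges`; the test-suite holds them to exact agreement with an
independent per-base bitmap oracle on randomised fixtures, and
`subtract_annotations()` preserves each surviving piece's attributes.

## Dark-matter mining

`select_probes()` applies the strict `>500 bp` and non-strict `>= 0.80`
identity rules, reading identity from the annotation's attribute (the
published criterion does not state whether similarity was measured over
the copy or the consensus; the annotation attribute is the operational
reading). The original study ran its annotation engine with the probe
library; here the scanner is an explicitly specified seed-and-extend
algorithm: exact `seed_k`-mer seeding (default 11) on both strands,
ungapped extension at +1/−1 with X-drop 20, acceptance at
`min_hit_identity` 0.60 and `min_hit_len` 20 bp (matching the 20-bp copy
floor). It is validated by recall on synthetic plants — ≥90 % of planted
bases at ≤15 % substitution divergence — not by reproducing any
genome-wide number. Because the synthetic mutation model is
substitution-only, a planted copy lies on a single alignment diagonal;
indel-containing real copies would fragment into several hits, which the
downstream merging stages absorb. `subtract_known()` guarantees zero
base overlap with the known annotation, and `classify_dm()` labels a
segment "extended" when it lies within `adjacency_gap` (default 0,
abutting) of a same-model annotation, else "new"; "extend" has no
published operational definition, so the gap is configurable.

## Permutation tests

`chromosome_enrichment()` formalises the published chromosome-level test
as a multinomial null: each of `n_perm` permutations (default 100 000)
assigns the genome-wide element total to chromosomes with probability
proportional to reduced size. The published description — the random
distribution of the number of elements in the reduced genome — names no
sampler; the multinomial is the natural formalisation of independent
uniform placement and is documented as this package's choice. A
coverage mode re-places individual element lengths instead of counts.
Calls use the empirical 1st/99th percentiles (the central 98 % box) with
strict inequalities. `n_perm < 100` is refused because the percentile
thresholds would be meaningless.

`hotspot_scan()` tiles chromosomes with non-overlapping 50-kbp windows
from position 1. Each permutation re-places the chromosome's copies
(lengths preserved) uniformly over non-N positions without overlap, by
rejection sampling capped at 10⁶ attempts (failure raises an explicit
error indicating that coverage is too high for non-overlapping
placement). Per-window counts pooled over all permutations and windows
of a chromosome form that chromosome's null — matching a single 1 %
threshold per chromosome — and a window is a hotspot when its observed
count strictly exceeds the 99th percentile. A copy is counted in the
window containing its start. Windows more than half N are excluded from
observed and null tallies, and a trailing short window is kept: the
original treatment of chromosome ends and N-heavy windows is unstated,
so both rules are package decisions. Both tests are seeded and fully
deterministic, and their type-I rates are checked on null-generated data
in the test-suite (≈2 % two-tailed for enrichment, ≤~1 % for hotspots,
within three Monte-Carlo standard deviations).

## Summary arithmetic

`kmer_size()` implements the sizing rule `l = log4(N) + 1` (16 nt for a
~1.05-Gbp genome); `cvalue_to_bp()` converts picograms at 0.978 Gbp/pg.
`model_table()`, `coverage_union_components()`, `fold_change()` and
`ssr_table()` reproduce the summary-table arithmetic; printed tables use
half-away-from-zero rounding (`1.2225 → 1.223` at three decimals), so
reporting helpers round half-up while machine outputs retain full
precision (`digits = NA`). `context_partition()` bins TE bases with the
priorities exon > genic > intergenic and inside > 3-kbp flank > rest;
"genic" is the gene span minus exons, flanks are clipped at chromosome
ends and at the elements themselves, and each scheme partitions the
annotated bases exactly. `te_density()` counts long-joined fragment
groups once, via the copy table.

## Synthetic genomes: what they emulate, and what not

`generate_genome()` is first-class, tested code, not a fixture: it
builds multi-chromosome genomes with i.i.d. uniform background (25 %
each base; GC is configurable only through the context features because
the compositional discussion in the source study is descriptive),
planted TE copies with per-copy divergence drawn uniformly from the
model's `divergence_range`, optional one-sided truncation removing
10–50 % of the copy, single-level nesting (one guest inside a host,
splitting the host into two truth features sharing a `copy_id` — exactly
the long-join situation), perfect SSR arrays of every class,
N-stretches placed only in background so truth stays exact, and
coordinate-only context tracks (genes with exons, CpG-like, S/MAR-like).
Everything is seeded and byte-reproducible, and the truth GFF3 uses the
same attribute schema the pipeline consumes.

Real data differ in ways the generator deliberately ignores: no indels,
no CpG-biased or lineage-structured mutation, no satellite
higher-order structure, no nested insertions deeper than one level.
Passing tests therefore demonstrate correctness of the algebra,
bookkeeping and statistics under substitution-style divergence — they do
not certify recall on genuinely rearranged genomic repeats.

## Problem sizes and numerical choices

The shipped tests exercise genomes of 30–180 kb with tens of planted
copies, 100 randomised algebra fixtures on ≤10-kb toy registries, 200
null replicates × 2000 permutations for enrichment calibration and 10 ×
1 Mb chromosomes × 1000 permutations for hotspot calibration — sizes
chosen so the whole suite runs in minutes on one core while keeping
Monte-Carlo error bands tight enough to be informative. Degenerate
inputs are defined rather than rejected wherever sensible: empty
sequences strip to empty indices, empty annotation sets have coverage 0,
a chromosome shorter than one window becomes a single truncated window,
and zero TEs yield zero thresholds and no hotspots.

## Known limitations

* The DM scanner is ungapped; heavily indel-diverged copies are
  recovered as fragments and their identity is computed per hit, not per
  copy.
* `find_exact_tandems()` is exact-match only and quadratic in
  `max_unit`; it is an oracle and fixture generator, not a detector for
  real data.
* The enrichment null treats elements as exchangeable points (or
  lengths); it does not model clustering within chromosomes, which is
  precisely what the hotspot scan is for.
* Venn coverage enumerates only non-empty membership combinations.
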