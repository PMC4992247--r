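# repeatscape

Tools for the post-processing layer of de novo repeat annotation in
assembled genomes — written for researchers re-annotating repeat
landscapes (SSRs, transposable elements, satellite DNA) in genome models
such as the ~1.05-Gbp chicken assembly, where library-based annotation
systematically under-reports old and fragmented repeats.

The heavy detectors (Tandem Repeats Finder, REPET-style consensus
builders, whole-genome repeat estimators) are consumed as file-level
inputs. `repeatscape` implements everything after them:

* **SSR typing** — parse TRF `.dat` output and apply the tandem-repeat
  taxonomy: 1-bp units are simple repeats (polyA/polyC), 2–10 bp
  microsatellites, 11–60 bp minisatellites (each retained with ≥50
  units), and >60-bp units are large tandem repeats (2–50 copies) or
  satellite DNAs (>50 copies).
* **Annotation algebra** — attribute-aware GFF3 interval operations:
  stack resolution (best identity, then consensus coverage), merging of
  juxtaposed same-model fragments, long-join copy counting (two
  fragments flanking a nested insertion count as one copy), the 20-bp
  minimum copy filter, and base-exact intersect/subtract/coverage/Venn.
* **Dark-matter mining** — use annotated copies >500 bp with ≥80 %
  identity as probes in a seed-and-extend scan (11-mer seeds, ungapped
  ±1 extension, X-drop 20), subtract known annotations, and label the
  remainder as new or extending.
* **N-gap remapping** — strip N-stretches before scanning and lift
  reported intervals back, splitting anything that spans a gap.
* **Permutation statistics** — chromosome-level over/under-representation
  on the *reduced genome* (size minus the element class's own coverage;
  empirical 1st/99th percentile calls from 100 000 permutations) and
  50-kbp-window TE hotspot detection (1000 non-overlapping re-placements
  over non-N space).
* **Summary arithmetic** — per-model copy/coverage tables, coverage
  union by inclusion–exclusion, fold changes, genomic-context partitions
  (exon/genic/intergenic; element/3-kbp-flank/rest), copy densities, the
  oligo-sizing rule `l = log4(N) + 1` and C-value-to-bp conversion
  (0.978 Gbp/pg).
* **A synthetic genome simulator** — multi-chromosome genomes with
  planted, ground-truthed TE copies (controlled divergence, truncation,
  single-level nesting), SSR arrays of every class, N-stretches and
  context tracks, so the whole pipeline is testable without downloads.

## Worked example

```r
library(repeatscape)

kmer_size(1047000000)                               # oligo size for a 1.047-Gbp model
#> [1] 16
fold_change(4.08, 1.73)                             # SSR coverage: TRF vs library-based
#> [1] 2.36
coverage_union_components(c(4.08, 15.7), 1.0)       # SSR + [TE+DM] minus double count
#> [1] 18.78

# A synthetic genome with planted, ground-truthed repeats
set.seed(1)
cons <- paste(sample(c("A","C","G","T"), 600, TRUE), collapse = "")
g <- generate_genome(
  c(chr1 = 50000, chr2 = 30000),
  te_specs  = list(repeat_model("CR1like", cons, "LINE", copy_count = 12,
                                divergence_range = c(0.05, 0.15),
                                nesting_prob = 0.2)),
  ssr_specs = list(ssr_plant("microsatellite", 3, 60, count = 4)),
  n_stretch = list(count = 2, min_len = 100, max_len = 300),
  seed = 7)
g
#> genome_truth: 2 chromosome(s), 80,000 bp, 18 planted repeat feature(s), 2 N-run(s), seed 7

# The five-step flow: SSRs, TE finishing, DM mining, final Venn coverage
te  <- g$truth[S4Vectors::mcols(g$truth)$class == "te"]
res <- run_pipeline(g$sequences, te, config = pipeline_config(seed = 7))
round(res$coverage, 4)
#>         SSR       TE_DM all_repeats
#>      0.0091      0.0933      0.1023
head(res$copies, 3)
#>     model seqid     copy_id n_fragments total_length
#> 1 CR1like  chr1 copy_000001           1          600
#> 2 CR1like  chr1 copy_000002           1          600
#> 3 CR1like  chr1 copy_000003           1          600

# Is either chromosome enriched in TE copies?
enr <- chromosome_enrichment(
  c(chr1 = sum(res$copies$seqid == "chr1"),
    chr2 = sum(res$copies$seqid == "chr2")),
  reduced_genome(c(chr1 = 50000, chr2 = 30000), te),
  n_perm = 10000, seed = 7)
enr
#>   unit observed expected low_threshold high_threshold call n_perm seed
#> 1 chr1        8   6.1184             3              9 none  10000    7
#> 2 chr2        2   3.8816             1              7 none  10000    7
```

The coverage vector is the fraction of the registered genome covered by
retained SSR arrays, by the finished TE+DM annotation, and by their
union; `copies` is the long-join-aware copy table (split host fragments
share one `copy_id`); the enrichment rows compare each chromosome's
observed copy count with the central 98 % of a 10 000-permutation
multinomial null over the reduced genome — here neither chromosome is
called.

See the methods vignette (`vignettes/repeat-annotation-methods.Rmd`) for
the model, parameter defaults and design decisions.

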