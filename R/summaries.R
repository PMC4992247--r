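#' Per-model copy and coverage summary table
#'
#' Builds the per-TE-model summary (consensuses, copies, percent of all
#' copies, percent of genome covered) from a copy table.
#'
#' @param copies Data.frame with columns `model`, `te_type`,
#'   `total_length` (bp per copy) and optionally `n_consensuses`; one row
#'   per copy, or pre-aggregated with an `n_copies` column.
#' @param genome_size Registered genome size (bp).
#' @param digits Decimals for the percent columns (half-up rounding, as
#'   printed tables use); `NA` keeps full precision.
#' @return Data.frame with `model`, `te_type`, `n_copies`,
#'   `percent_of_copies`, `percent_coverage`, plus a `Total` row.
#' @export
model_table <- function(copies, genome_size, digits = 4) {
  if (!is.null(copies$n_copies)) {
    agg <- copies
    if (is.null(agg$bases)) agg$bases <- agg$total_length
  } else {
    agg <- do.call(rbind, lapply(split(copies, copies$model), function(d) {
      data.frame(model = d$model[1],
                 te_type = d$te_type[1] %||% NA_character_,
                 n_copies = nrow(d),
                 bases = sum(d$total_length))
    }))
  }
  tot_copies <- sum(agg$n_copies)
  out <- data.frame(
    model = agg$model, te_type = agg$te_type, n_copies = agg$n_copies,
    percent_of_copies = 100 * agg$n_copies / tot_copies,
    percent_coverage = 100 * agg$bases / genome_size
  )
  out <- out[order(out$model), , drop = FALSE]
  out <- rbind(out, data.frame(model = "Total", te_type = NA,
                               n_copies = tot_copies,
                               percent_of_copies = 100,
                               percent_coverage = 100 * sum(agg$bases) /
                                 genome_size))
  if (!is.na(digits)) {
    out$percent_of_copies <- round_half_up(out$percent_of_copies, digits)
    out$percent_coverage <- round_half_up(out$percent_coverage, digits)
  }
  rownames(out) <- NULL
  out
}

#' Combine component coverages by inclusion-exclusion
#'
#' Adds named component coverages and subtracts pairwise overlap
#' corrections, e.g. SSR + \[TE+DM\] - (SSR within \[TE+DM\]). When full
#' annotation sets are available, [venn_coverage()] computes the same
#' quantity from base-level overlaps; the two paths agree.
#'
#' @param components Numeric vector of component coverages (percent or
#'   fraction, any consistent scale).
#' @param overlaps Numeric vector of double-counted overlap coverages to
#'   subtract.
#' @return The combined coverage on the input scale.
#' @examples
#' coverage_union_components(c(4.08, 15.7), overlaps = 1.0)  # 18.78
#' @export
coverage_union_components <- function(components, overlaps = 0) {
  sum(components) - sum(overlaps)
}

#' Fold change between two coverages
#'
#' @param a,b Coverages (same scale).
#' @param digits Decimals (half-up); `NA` for full precision.
#' @return `a / b`, rounded.
#' @examples
#' fold_change(4.08, 1.73)   # 2.36
#' @export
fold_change <- function(a, b, digits = 2) {
  r <- a / b
  if (is.na(digits)) r else round_half_up(r, digits)
}

#' Oligo (k-mer) size for repeat scanning
#'
#' The scanning oligo length for a genome of `genome_length` bp is
#' `l = log4(N) + 1`, rounded to the nearest integer — 16 nt for a
#' ~1-Gbp genome.
#'
#' @param genome_length Genome size N in bp.
#' @return Integer oligo length.
#' @examples
#' kmer_size(1047000000)  # 16
#' @export
kmer_size <- function(genome_length) {
  as.integer(round(log(genome_length, base = 4) + 1))
}

#' Convert a C-value to base pairs
#'
#' Haploid DNA content in picograms converts to bp at 0.978 x 10^9 bp
#' per pg.
#'
#' @param pg C-value in picograms.
#' @return Genome size in bp.
#' @examples
#' cvalue_to_bp(1.25) / 1e9   # 1.2225 Gbp (prints as 1.223 at 3 decimals)
#' @export
cvalue_to_bp <- function(pg) {
  pg * 0.978e9
}

#' Partition TE bases by genomic context
#'
#' Assigns every annotated TE base to exactly one bin in each of two
#' schemes: (1) exon > genic > intergenic, where "genic" is the gene span
#' minus exons and intergenic the complement; (2) inside element > 3-kbp
#' flank > rest, for context elements such as CpG islands or S/MARs
#' (flanks are clipped at chromosome ends and at the elements
#' themselves). Within each scheme the bins partition the TE bases
#' exactly.
#'
#' @param te TE annotation set (registered).
#' @param genes `GRanges` of gene spans.
#' @param exons `GRanges` of exons.
#' @param elements Optional `GRanges` of context elements (CpG/S-MAR).
#' @param flank Flank size (bp) for the element scheme.
#' @return List with `gene_scheme` and (if `elements` given)
#'   `element_scheme`, each a named vector of base counts.
#' @export
context_partition <- function(te, genes, exons,
                              elements = NULL, flank = 3000) {
  ter <- GenomicRanges::reduce(te, ignore.strand = TRUE)
  total <- sum(as.numeric(GenomicRanges::width(ter)))
  bp_in <- function(regions) {
    if (!length(regions)) return(0)
    sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(ter,
                               GenomicRanges::reduce(regions,
                                                     ignore.strand = TRUE),
                               ignore.strand = TRUE))))
  }
  exr <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  genr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(genes, ignore.strand = TRUE), exr,
    ignore.strand = TRUE)
  exonic <- bp_in(exr)
  genic <- bp_in(genr)
  res <- list(gene_scheme = c(exon = exonic, genic = genic,
                              intergenic = total - exonic - genic))
  if (!is.null(elements)) {
    elr <- GenomicRanges::reduce(elements, ignore.strand = TRUE)
    fl <- GenomicRanges::setdiff(
      suppressWarnings(GenomicRanges::trim(
        GenomicRanges::resize(elr, GenomicRanges::width(elr) + 2L * flank,
                              fix = "center"))),
      elr, ignore.strand = TRUE)
    inside <- bp_in(elr)
    flankb <- bp_in(fl)
    res$element_scheme <- c(inside = inside, flank = flankb,
                            rest = total - inside - flankb)
  }
  res
}

#' TE copy density per chromosome
#'
#' Copies per Mbp, counting long-joined fragment groups once (the copy
#' table from [long_join_copies()] already has one row per copy).
#'
#' @param copies Copy table with a `seqid` column (one row per copy).
#' @param chrom_sizes Named vector of chromosome sizes (bp).
#' @return Data.frame with `seqid`, `n_copies`, `density_per_mbp`.
#' @export
te_density <- function(copies, chrom_sizes) {
  n <- setNames(integer(length(chrom_sizes)), names(chrom_sizes))
  tab <- table(copies$seqid)
  n[names(tab)] <- as.integer(tab)
  data.frame(seqid = names(chrom_sizes), n_copies = as.integer(n),
             density_per_mbp = as.numeric(n) /
               (as.numeric(chrom_sizes) / 1e6),
             row.names = NULL)
}

#' SSR census table
#'
#' Per-class array counts, distinct-unit counts (100 % identity) and
#' genome coverage, from a classified array table.
#'
#' @param arrays Classified array table (see [classify_arrays()]).
#' @param genome_size Registered genome size (bp).
#' @return Data.frame with one row per retained SSR class.
#' @export
ssr_table <- function(arrays, genome_size) {
  keep <- arrays[arrays$ssr_class != "rejected", , drop = FALSE]
  out <- do.call(rbind, lapply(split(keep, keep$ssr_class), function(d) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      d$seqid, IRanges::IRanges(d$start, d$end)))
    data.frame(ssr_class = d$ssr_class[1], n_arrays = nrow(d),
               n_distinct_units = distinct_units(d$unit),
               percent_coverage = 100 *
                 sum(as.numeric(GenomicRanges::width(gr))) / genome_size)
  }))
  rownames(out) <- NULL
  out
}
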