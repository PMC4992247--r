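#' Default pipeline configuration
#'
#' All thresholds of the five-step repeat-annotation flow with their
#' standard defaults: TRF parameters (2,5,7,80,10,25,2000), 50-unit SSR
#' retention, 20-bp minimum TE copy, >500-bp / >=80 %-identity DM probes,
#' 50-kbp hotspot windows and the permutation counts.
#'
#' @param ... Overrides for individual entries.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    trf_params = c(match = 2, mismatch = 5, delta = 7, pm = 80, pi = 10,
                   minscore = 25, maxperiod = 2000),
    ssr_min_units = 50,
    min_copy_len = 20,
    merge_max_gap = 0,
    long_join_span = 10000,
    probe_min_len = 500,
    probe_min_identity = 0.80,
    dm_seed_k = 11,
    dm_min_hit_identity = 0.60,
    dm_min_hit_len = 20,
    dm_x_drop = 20,
    enrich_n_perm = 100000,
    hotspot_window = 50000,
    hotspot_n_perm = 1000,
    alpha = 0.01,
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return A `pipeline_config` with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the five-step repeat annotation flow on a genome
#'
#' Orchestrates the post-processing pipeline on in-memory inputs:
#' (1) an overall repeat estimate (coverage of all planted/known repeat
#' annotations, or skipped when none are given); (2) SSR detection and
#' classification; (3) TE annotation finishing (stack resolution,
#' juxtaposition merging, 20-bp minimum size, long-join copy counting);
#' (4) dark-matter mining with conserved probe copies and subtraction of
#' known annotations; (5) merge of an externally supplied CNV track.
#' The consensus-building stages themselves (de novo repeat detection)
#' are external: this function consumes their outputs (`te_annotations`)
#' or synthetic stand-ins. Every stage logs feature counts in the audit
#' log, and a final Venn coverage table over \{SSR, TE+DM, CNV\} is
#' produced.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param te_annotations Annotation set of TE copies with `model`,
#'   `identity` (fraction), optionally `consensus` columns.
#' @param cnv Optional `GRanges` of CNV annotations.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for GFF3/TSV artifacts and the run
#'   manifest.
#' @param trf_dat Optional path to a TRF `.dat` file to use for step 2
#'   instead of the built-in exact-tandem detector.
#' @return A list with `ssr` (classified array table), `ssr_gff`,
#'   `te_resolved`, `te_merged`, `te_filtered`, `copies` (long-join copy
#'   table), `dm` (classified DM set), `venn`, `coverage` (named
#'   fractions), and `audit` (stage-by-stage counts).
#' @export
run_pipeline <- function(genome, te_annotations, cnv = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         trf_dat = NULL) {
  set.seed(config$seed)
  sl <- setNames(Biostrings::width(genome), names(genome))
  audit <- list()
  note <- function(stage, ...) {
    audit[[stage]] <<- c(...)
  }

  # Step 2: SSRs
  arrays <- if (!is.null(trf_dat)) {
    parse_trf_dat(trf_dat)
  } else {
    do.call(rbind, lapply(names(genome), function(ch) {
      find_exact_tandems(as.character(genome[[ch]]), max_unit = 100,
                         min_copies = 2, seqid = ch)
    }))
  }
  arrays <- classify_arrays(arrays, min_units_small = config$ssr_min_units)
  ssr_gff <- ssr_to_gff(arrays, sl)
  note("ssr", detected = nrow(arrays), retained = length(ssr_gff))

  # Step 3: TE finishing
  te <- annotation_set(te_annotations, sl)
  resolved <- resolve_stacks(te)
  merged <- merge_juxtaposed(resolved, max_gap = config$merge_max_gap)
  filtered <- filter_min_length(merged, min_len = config$min_copy_len)
  lj <- long_join_copies(filtered, max_nested_span = config$long_join_span)
  note("te", input = length(te), resolved = length(resolved),
       merged = length(merged), filtered = length(filtered),
       copies = nrow(lj$copies))

  # Step 4: dark matter
  probes <- select_probes(te, genome, min_len = config$probe_min_len,
                          min_identity = config$probe_min_identity)
  known <- GenomicRanges::reduce(
    c(GenomicRanges::granges(ssr_gff), GenomicRanges::granges(filtered)),
    ignore.strand = TRUE)
  known <- annotation_set(known, sl)
  if (nrow(probes)) {
    hits <- homology_scan(probes, genome, seed_k = config$dm_seed_k,
                          min_hit_identity = config$dm_min_hit_identity,
                          min_hit_len = config$dm_min_hit_len,
                          x_drop = config$dm_x_drop)
    dm <- subtract_known(hits, known)
    dm <- filter_min_length(dm, min_len = config$dm_min_hit_len)
    dm <- classify_dm(dm, filtered)
  } else {
    hits <- dm <- annotation_set(GenomicRanges::GRanges(), sl)
  }
  note("dm", probes = nrow(probes), hits = length(hits),
       after_subtraction = length(dm))

  # Step 5: CNV merge + final Venn
  sets <- list(SSR = ssr_gff,
               TE_DM = c(GenomicRanges::granges(filtered),
                         GenomicRanges::granges(dm)))
  if (!is.null(cnv) && length(cnv)) {
    sets$CNV <- annotation_set(GenomicRanges::granges(cnv), sl)
  }
  sets <- lapply(sets, annotation_set, seq_lengths = sl)
  venn <- venn_coverage(sets)
  cov <- vapply(sets, coverage_fraction, numeric(1))
  cov["all_repeats"] <- do.call(union_coverage, unname(sets))
  note("final", union_coverage = unname(cov["all_repeats"]))

  res <- list(ssr = arrays, ssr_gff = ssr_gff, te_resolved = resolved,
              te_merged = merged, te_filtered = filtered,
              copies = lj$copies, dm = dm, venn = venn, coverage = cov,
              audit = audit, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gff3_annotations(ssr_gff, file.path(out_dir, "ssr.gff3"))
    write_gff3_annotations(lj$features, file.path(out_dir, "te.gff3"))
    if (length(dm)) {
      write_gff3_annotations(dm, file.path(out_dir, "dm.gff3"))
    }
    write.table(lj$copies, file.path(out_dir, "copies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(venn, file.path(out_dir, "venn.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    manifest <- list(seed = config$seed,
                     genome_sequences = length(genome),
                     genome_bp = sum(as.numeric(sl)),
                     audit = audit,
                     coverage = as.list(cov))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
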