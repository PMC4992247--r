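test_that("scanning oligo size follows l = log4(N) + 1", {
  expect_equal(kmer_size(1047000000), 16L)
  expect_equal(kmer_size(4), 2L)
  # monotone over a grid of genome sizes
  grid <- 10^seq(3, 10, by = 0.25)
  expect_true(all(diff(kmer_size(grid)) >= 0))
})

test_that("C-value conversion is linear at 0.978 Gbp per pg", {
  expect_equal(cvalue_to_bp(1.25), 1.2225e9)
  expect_equal(cvalue_to_bp(0), 0)
  expect_equal(cvalue_to_bp(2 * 1.7), 2 * cvalue_to_bp(1.7))
  # printed at 3 decimals in Gbp this reports 1.223
  expect_equal(round_half_up <- repeatscape:::round_half_up(
    cvalue_to_bp(1.25) / 1e9, 3), 1.223)
})

test_that("fold changes and inclusion-exclusion unions reproduce table arithmetic", {
  expect_equal(fold_change(4.08, 1.73), 2.36)
  expect_equal(fold_change(3.73, 1.54), 2.42)
  expect_equal(fold_change(18.78, 11.47), 1.64)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(coverage_union_components(c(4.08, 15.7), 1.0), 18.78)
  expect_equal(coverage_union_components(c(2, 3)), 5)  # disjoint -> plain sum
})

test_that("component union equals the base-level Venn union on real sets", {
  sl <- c(chr1 = 20000L)
  set.seed(61)
  for (rep in 1:10) {
    a_df <- random_intervals(15, sl)
    b_df <- random_intervals(15, sl)
    a <- annotation_set(a_df, sl); b <- annotation_set(b_df, sl)
    ov <- sum(GenomicRanges::width(intersect_annotations(a, b))) /
      sum(as.numeric(sl))
    via_formula <- coverage_union_components(
      c(coverage_fraction(a), coverage_fraction(b)), ov)
    expect_equal(via_formula, union_coverage(a, b))
    expect_equal(via_formula, sum(venn_coverage(list(A = a, B = b))$coverage))
  }
})

test_that("model summary table computes copy and coverage percentages", {
  copies <- data.frame(
    model = c("CR1", "Charlie-Galluhop", "Other"),
    te_type = c("LINE", "TIR", "LTR"),
    n_copies = c(413857, 67691, 141068),
    bases = c(124e6, 10.8e6, 34e6))
  tab <- model_table(copies, genome_size = 1.047e9)
  expect_equal(tab$percent_of_copies[tab$model == "CR1"], 66.4707)
  expect_equal(tab$percent_of_copies[tab$model == "Charlie-Galluhop"],
               10.872)
  expect_equal(tab$n_copies[tab$model == "Total"], 622616)
  expect_equal(tab$percent_of_copies[tab$model == "Total"], 100)
  # single model -> 100 %
  tab1 <- model_table(data.frame(model = "X", te_type = "LINE",
                                 n_copies = 5, bases = 1000), 1e6)
  expect_equal(tab1$percent_of_copies[1], 100)
  # full-precision column sums to 100 within rounding
  raw <- model_table(copies, 1.047e9, digits = NA)
  expect_equal(sum(raw$percent_of_copies[raw$model != "Total"]), 100)
})

test_that("per-copy tables aggregate to the same summary", {
  percopy <- data.frame(
    model = rep(c("A", "B"), c(3, 1)), te_type = rep(c("TIR", "LTR"), c(3, 1)),
    total_length = c(100, 200, 300, 400))
  tab <- model_table(percopy, genome_size = 1e5, digits = NA)
  expect_equal(tab$n_copies[tab$model == "A"], 3)
  expect_equal(tab$percent_coverage[tab$model == "A"], 100 * 600 / 1e5)
  expect_equal(tab$percent_of_copies[tab$model == "B"], 25)
})

test_that("TE bases partition exactly over genomic context bins", {
  sl <- c(chr1 = 50000L)
  te <- annotation_set(data.frame(
    seqid = "chr1", start = c(1000, 5000, 20000), end = c(1499, 5999, 20999)),
    sl)
  genes <- annotation_set(data.frame(seqid = "chr1", start = 900,
                                     end = 6500), sl)
  exons <- annotation_set(data.frame(seqid = "chr1", start = c(950, 5500),
                                     end = c(1600, 5700)), sl)
  cp <- context_partition(te, genes, exons)
  # TE1 wholly inside an exon
  expect_equal(unname(cp$gene_scheme["exon"]), 500 + 201)
  expect_equal(unname(cp$gene_scheme["genic"]), 1000 - 201)
  expect_equal(unname(cp$gene_scheme["intergenic"]), 1000)
  expect_equal(sum(cp$gene_scheme), sum(GenomicRanges::width(te)))

  # element scheme with flanks clipped at the element
  el <- annotation_set(data.frame(seqid = "chr1", start = 20500,
                                  end = 20600), sl)
  cp2 <- context_partition(te, genes, exons, elements = el, flank = 300)
  expect_equal(unname(cp2$element_scheme["inside"]), 101)
  # TE3 (20000-20999) fully covers both 300-bp flanks of the element
  expect_equal(unname(cp2$element_scheme["flank"]), 600)
  expect_equal(sum(cp2$element_scheme), sum(GenomicRanges::width(te)))

  # bitmap oracle on random fixtures
  set.seed(62)
  for (rep in 1:10) {
    te_df <- random_intervals(20, sl)
    gene_df <- random_intervals(6, sl, max_len = 4000)
    exon_df <- random_intervals(8, sl, max_len = 800)
    cp3 <- context_partition(annotation_set(te_df, sl),
                             annotation_set(gene_df, sl),
                             annotation_set(exon_df, sl))
    bm_te <- bitmap_from_df(te_df, sl)
    bm_ex <- bitmap_from_df(exon_df, sl)
    bm_gn <- bitmap_diff(bitmap_from_df(gene_df, sl), bm_ex)
    expect_equal(unname(cp3$gene_scheme["exon"]),
                 bitmap_bases(bitmap_and(bm_te, bm_ex)))
    expect_equal(unname(cp3$gene_scheme["genic"]),
                 bitmap_bases(bitmap_and(bm_te, bm_gn)))
    expect_equal(sum(cp3$gene_scheme), bitmap_bases(bm_te))
  }
})

test_that("TE density counts long-joined copies once", {
  copies <- data.frame(seqid = c("chr1", "chr1", "chr2"),
                       model = "M", copy_id = c("c1", "c2", "c3"))
  d <- te_density(copies, c(chr1 = 1e7, chr2 = 5e6))
  expect_equal(d$density_per_mbp, c(0.2, 0.2))
  # nested fixture: split host counted once through the copy table
  sl <- c(chr1 = 10000L)
  df <- data.frame(seqid = "chr1", start = c(1000, 2500, 1500),
                   end = c(1499, 2999, 2499), model = c("H", "H", "G"),
                   identity = 90, consensus = c("h", "h", "g"))
  lj <- long_join_copies(annotation_set(df, sl))
  d2 <- te_density(lj$copies, c(chr1 = 1e6))
  expect_equal(d2$n_copies, 2L)
})

test_that("SSR census table is internally consistent", {
  arrays <- data.frame(
    seqid = "chr1", start = c(1, 101, 201, 401),
    end = c(60, 180, 260, 460),
    unit_length = c(1, 3, 3, 120), copy_number = c(60, 60, 20, 51),
    unit = c("A", "ACT", "AGT", strrep("A", 120)))
  arrays <- classify_arrays(arrays)
  tab <- ssr_table(arrays, genome_size = 10000)
  expect_setequal(tab$ssr_class, c("simple_polyA", "microsatellite",
                                   "satellite"))
  micro <- tab[tab$ssr_class == "microsatellite", ]
  expect_equal(micro$n_arrays, 1L)   # the 20-copy array was rejected
  expect_equal(micro$percent_coverage, 100 * 80 / 10000)
})
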