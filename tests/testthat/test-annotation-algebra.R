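sl_toy <- c(chr1 = 10000L, chr2 = 8000L)

test_that("annotation sets require a complete genome registry", {
  df <- data.frame(seqid = "chrX", start = 1, end = 10)
  expect_error(annotation_set(df, sl_toy), "unregistered")
  gr <- annotation_set(data.frame(seqid = "chr1", start = 1, end = 10),
                       sl_toy)
  expect_equal(unname(GenomeInfoDb::seqlengths(gr)["chr1"]), 10000L)
  expect_error(coverage_fraction(GenomicRanges::GRanges(
    "z", IRanges::IRanges(1, 5))), "unregistered")
})

test_that("stack resolution keeps the single best feature per stack", {
  df <- data.frame(seqid = "chr1", start = c(100, 100), end = c(200, 200),
                   model = "M", identity = c(85, 70),
                   consensus = c("a", "b"), consensus_coverage = c(0.5, 0.9))
  out <- resolve_stacks(annotation_set(df, sl_toy))
  expect_length(out, 1L)
  expect_equal(S4Vectors::mcols(out)$identity, 85)

  # single feature unchanged
  one <- annotation_set(df[1, ], sl_toy)
  expect_equal(length(resolve_stacks(one)), 1L)

  # missing identity treated as 0, with a message
  df2 <- df; df2$identity[1] <- NA
  expect_message(out2 <- resolve_stacks(annotation_set(df2, sl_toy)),
                 "missing identity")
  expect_equal(S4Vectors::mcols(out2)$identity, 70)
})

test_that("stack resolution matches brute-force enumeration on random stacks", {
  set.seed(91)
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    start <- sample.int(500, k, replace = TRUE)
    df <- data.frame(
      seqid = "chr1", start = start,
      end = start + sample.int(120, k, replace = TRUE),
      model = sample(c("M1", "M2"), k, replace = TRUE),
      identity = sample(c(60, 75, 75, 90), k, replace = TRUE),
      consensus = sample(letters[1:3], k, replace = TRUE),
      consensus_coverage = sample(c(0.2, 0.5, 0.5, 0.9), k, replace = TRUE))
    out <- resolve_stacks(annotation_set(df, sl_toy))
    want <- df[oracle_resolve(df), , drop = FALSE]
    want <- want[order(want$start, want$end), , drop = FALSE]
    expect_equal(length(out), nrow(want))
    expect_equal(GenomicRanges::start(out), want$start)
    expect_equal(S4Vectors::mcols(out)$identity, want$identity)
    # no same-model overlaps remain, and the operation is idempotent
    for (mod in unique(df$model)) {
      sub <- out[S4Vectors::mcols(out)$model == mod]
      if (length(sub) > 1) {
        expect_true(all(IRanges::countOverlaps(sub, sub) == 1))
      }
    }
    expect_equal(length(resolve_stacks(out)), length(out))
  }
})

test_that("juxtaposed same-model features merge across small gaps", {
  df <- data.frame(seqid = "chr1", start = c(100, 200), end = c(199, 299),
                   model = "M", identity = c(90, 80),
                   consensus = c("a", "b"))
  out <- merge_juxtaposed(annotation_set(df, sl_toy))
  expect_length(out, 1L)
  expect_equal(GenomicRanges::start(out), 100L)
  expect_equal(GenomicRanges::end(out), 299L)
  expect_equal(S4Vectors::mcols(out)$consensus, "a,b")

  # different models never merge
  df$model <- c("M1", "M2")
  expect_length(merge_juxtaposed(annotation_set(df, sl_toy)), 2L)

  # a gap wider than max_gap keeps features apart
  df3 <- data.frame(seqid = "chr1", start = c(100, 205), end = c(199, 299),
                    model = "M", identity = 90, consensus = "a")
  expect_length(merge_juxtaposed(annotation_set(df3, sl_toy)), 2L)
  expect_length(merge_juxtaposed(annotation_set(df3, sl_toy), max_gap = 5), 1L)
})

test_that("chains of adjacent features collapse regardless of input order", {
  set.seed(17)
  k <- 5
  df <- data.frame(seqid = "chr1", start = 100 + 50 * (0:(k - 1)),
                   end = 100 + 50 * (1:k) - 1, model = "M",
                   identity = 90, consensus = letters[1:k])
  for (rep in 1:5) {
    shuf <- df[sample.int(k), , drop = FALSE]
    out <- merge_juxtaposed(annotation_set(shuf, sl_toy))
    expect_length(out, 1L)
    expect_equal(S4Vectors::mcols(out)$consensus,
                 paste(letters[1:k], collapse = ","))
    expect_equal(length(merge_juxtaposed(out)), 1L)  # idempotent
  }
})

test_that("long-join counting treats fragments flanking a nested TE as one copy", {
  df <- data.frame(seqid = "chr1",
                   start = c(1000, 2500, 1500), end = c(1499, 2999, 2499),
                   model = c("H", "H", "G"), identity = 90,
                   consensus = c("h", "h", "g"))
  lj <- long_join_copies(annotation_set(df, sl_toy))
  expect_equal(nrow(lj$copies), 2L)
  hostrow <- lj$copies[lj$copies$model == "H", ]
  expect_equal(hostrow$n_fragments, 2L)
  expect_equal(hostrow$total_length, 1000L)
  expect_equal(lj$copies$total_length[lj$copies$model == "G"], 1000L)

  # no guest between the fragments -> two copies
  df2 <- df[1:2, ]
  lj2 <- long_join_copies(annotation_set(df2, sl_toy))
  expect_equal(nrow(lj2$copies), 2L)

  # gap beyond max_nested_span -> two copies even with a guest
  lj3 <- long_join_copies(annotation_set(df, sl_toy),
                          max_nested_span = 500)
  expect_equal(nrow(lj3$copies[lj3$copies$model == "H", ]), 2L)
})

test_that("minimum-length filtering removes sub-threshold features", {
  df <- data.frame(seqid = "chr1", start = c(1, 100), end = c(19, 119))
  gr <- annotation_set(df, sl_toy)
  expect_message(out <- filter_min_length(gr, 20), "removed 1")
  expect_length(out, 1L)
  expect_equal(GenomicRanges::width(out), 20L)
  expect_length(filter_min_length(gr[0], 20), 0L)
})

test_that("set operations have exact per-base bitmap semantics", {
  set.seed(23)
  for (rep in 1:30) {
    a_df <- random_intervals(sample(5:30, 1), sl_toy)
    b_df <- random_intervals(sample(5:30, 1), sl_toy)
    a <- annotation_set(a_df, sl_toy)
    b <- annotation_set(b_df, sl_toy)
    bm_a <- bitmap_from_df(a_df, sl_toy)
    bm_b <- bitmap_from_df(b_df, sl_toy)

    expect_equal(sum(GenomicRanges::width(intersect_annotations(a, b))),
                 bitmap_bases(bitmap_and(bm_a, bm_b)))
    sub <- subtract_annotations(a, b)
    expect_equal(bitmap_bases(bitmap_from_gr(sub, sl_toy)),
                 bitmap_bases(bitmap_diff(bm_a, bm_b)))
    expect_equal(union_coverage(a, b),
                 bitmap_coverage(bitmap_or(bm_a, bm_b)))
    expect_equal(coverage_fraction(a), bitmap_coverage(bm_a))
    # conservation: coverage(A) = coverage(A^B) + coverage(A\B)
    cov_int <- sum(GenomicRanges::width(intersect_annotations(a, b))) /
      sum(as.numeric(sl_toy))
    cov_sub <- bitmap_bases(bitmap_from_gr(sub, sl_toy)) /
      sum(as.numeric(sl_toy))
    expect_equal(coverage_fraction(a), cov_int + cov_sub)
  }
  # degenerate identities
  x <- annotation_set(random_intervals(10, sl_toy), sl_toy)
  expect_length(subtract_annotations(x, x), 0L)
  ix <- intersect_annotations(x, x)
  expect_equal(sum(GenomicRanges::width(ix)),
               sum(GenomicRanges::width(GenomicRanges::reduce(x))))
  expect_equal(coverage_fraction(x[0]), 0)
})

test_that("Venn coverage partitions the union into disjoint regions", {
  a <- annotation_set(data.frame(seqid = "chr1", start = 1, end = 100),
                      sl_toy)
  b <- annotation_set(data.frame(seqid = "chr1", start = 201, end = 300),
                      sl_toy)
  v <- venn_coverage(list(A = a, B = b))
  expect_equal(nrow(v), 2L)       # two singleton regions, no intersection
  expect_setequal(v$members, c("A", "B"))

  v2 <- venn_coverage(list(A = a, B = a))
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$members, "A,B")

  set.seed(5)
  for (rep in 1:10) {
    sets <- list(X = random_intervals(15, sl_toy),
                 Y = random_intervals(15, sl_toy),
                 Z = random_intervals(15, sl_toy))
    v <- venn_coverage(lapply(sets, annotation_set, seq_lengths = sl_toy))
    bms <- lapply(sets, bitmap_from_df, seq_lengths = sl_toy)
    # every membership combination agrees with the bitmap oracle
    for (i in seq_len(nrow(v))) {
      mem <- strsplit(v$members[i], ",")[[1]]
      bm <- Reduce(bitmap_and, bms[mem])
      for (o in setdiff(names(sets), mem)) bm <- bitmap_diff(bm, bms[[o]])
      expect_equal(v$coverage[i], bitmap_coverage(bm))
    }
    expect_equal(sum(v$coverage),
                 bitmap_coverage(Reduce(bitmap_or, bms)))
  }
})

test_that("set operations are invariant to feature order", {
  set.seed(31)
  df <- random_intervals(20, sl_toy)
  df$model <- sample(c("M1", "M2"), 20, TRUE)
  df$identity <- sample(50:99, 20, TRUE)
  df$consensus <- sample(letters[1:4], 20, TRUE)
  df$consensus_coverage <- runif(20)
  perm <- df[sample.int(20), , drop = FALSE]
  a1 <- annotation_set(df, sl_toy); a2 <- annotation_set(perm, sl_toy)
  expect_equal(resolve_stacks(a1), resolve_stacks(a2))
  expect_equal(merge_juxtaposed(a1), merge_juxtaposed(a2))
  expect_equal(coverage_fraction(a1), coverage_fraction(a2))
})
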