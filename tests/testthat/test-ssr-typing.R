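make_dat_lines <- function() {
  c("Tandem Repeats Finder Program",
    "",
    "Sequence: chr1",
    "",
    "Parameters: 2 5 7 80 10 25 2000",
    "",
    "101 280 3 60.0 3 95 0 100 25 25 25 25 1.9 ACT ACTACTACT",
    "500 580 1 80.0 1 100 0 42 100 0 0 0 0.0 A AAAAAAA",
    "900 1100 10 20.1 10 90 2 300 25 25 25 25 2.0 ACGTACGTTT ACGTACGTTT",
    "Sequence: chr2",
    "",
    "10 80 7 10.1 7 88 1 100 25 25 25 25 2.0 ACGTAAA ACGTAAA",
    "200 260 2 30.5 2 99 0 120 50 0 0 50 1.0 AT ATATAT",
    "300 1000 70 10.0 70 92 0 150 25 25 25 25 2.0 ACGTACGTACGT ACGT")
}

test_that("TRF .dat parsing attributes records to the right sequence", {
  expect_equal(nrow(parse_trf_dat(character(0))), 0L)

  f <- tempfile(fileext = ".dat")
  writeLines(make_dat_lines(), f)
  suppressMessages(arr <- parse_trf_dat(f))
  expect_equal(nrow(arr), 6L)
  expect_equal(arr$seqid, c(rep("chr1", 3), rep("chr2", 3)))
  expect_equal(arr$start[1], 101L)
  expect_equal(arr$copy_number[5], 30.5)
  expect_equal(arr$unit[1], "ACT")

  bad <- c("Sequence: chr1", "101 160 3 20.0 3 95 0 100 25 25")
  expect_error(parse_trf_dat(bad), "line 2")
  expect_error(parse_trf_dat("1 2 3 4 5 6 7 8 9 10 11 12 13 A B"),
               "Sequence")
})

test_that("SSR taxonomy assigns each array to exactly one class", {
  expect_equal(classify_ssr(5, 60), "microsatellite")
  expect_equal(classify_ssr(1, 49, "A"), "rejected")
  expect_equal(classify_ssr(1, 50, "T"), "simple_polyA")
  expect_equal(classify_ssr(1, 50, "G"), "simple_polyC")
  expect_equal(classify_ssr(120, 51), "satellite")
  expect_equal(classify_ssr(120, 50), "large_tandem_repeat")
  expect_equal(classify_ssr(11, 50), "minisatellite")
  expect_equal(classify_ssr(61, 2), "large_tandem_repeat")
  # fractional TRF copy numbers compared directly to thresholds
  expect_equal(classify_ssr(4, 49.9), "rejected")
  expect_equal(classify_ssr(4, 50.0), "microsatellite")
  expect_equal(classify_ssr(70, 50.3), "satellite")

  # class partition over a boundary grid: every retained array has
  # exactly one class and class counts sum to the retained count
  grid <- expand.grid(unit_length = c(1, 2, 10, 11, 60, 61, 120),
                      copy_number = c(2, 49, 50, 51))
  cls <- classify_ssr(grid$unit_length, grid$copy_number, "A")
  expect_true(all(cls %in% c("simple_polyA", "simple_polyC",
                             "microsatellite", "minisatellite",
                             "large_tandem_repeat", "satellite",
                             "rejected")))
  retained <- cls != "rejected"
  expect_equal(sum(table(cls[retained])), sum(retained))
})

test_that("raising the small-array retention threshold never retains more", {
  set.seed(7)
  ul <- sample(c(1:12, 60, 61, 120), 200, TRUE)
  cn <- runif(200, 2, 120)
  kept <- function(mu) {
    sum(classify_ssr(ul, cn, "A", min_units_small = mu) != "rejected")
  }
  ks <- vapply(c(10, 30, 50, 70, 90), kept, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("classified arrays round-trip through the six-attribute GFF3", {
  f <- tempfile(fileext = ".dat")
  writeLines(make_dat_lines(), f)
  suppressMessages(arr <- classify_arrays(parse_trf_dat(f)))
  gr <- ssr_to_gff(arr, c(chr1 = 2000L, chr2 = 1000L))
  expect_equal(length(gr), sum(arr$ssr_class != "rejected"))
  mc <- S4Vectors::mcols(gr)
  expect_true(all(c("ID", "ssr_type", "unit_size", "unit_seq",
                    "array_size", "copy_number") %in% colnames(mc)))
  gff <- tempfile(fileext = ".gff3")
  write_gff3_annotations(gr, gff)
  back <- read_gff3_annotations(gff, c(chr1 = 2000L, chr2 = 1000L))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(as.character(S4Vectors::mcols(back)$ssr_type),
               as.character(mc$ssr_type))
  expect_equal(as.numeric(S4Vectors::mcols(back)$copy_number),
               as.numeric(mc$copy_number))

  # empty input -> empty set
  empty <- arr[arr$ssr_class == "rejected" & arr$unit_length > 9999, ]
  expect_length(ssr_to_gff(classify_arrays(empty)), 0L)
})

test_that("exact-tandem oracle reports maximal primitive-unit arrays", {
  t1 <- find_exact_tandems("ACACACAC", max_unit = 4)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$unit, "AC")
  expect_equal(t1$copy_number, 4)

  t2 <- find_exact_tandems("AAAA", max_unit = 2)
  expect_equal(t2$unit, "A")     # primitive unit, not "AA" x 2
  expect_equal(t2$copy_number, 4)

  t3 <- find_exact_tandems("GGACTACTACTACTGG", max_unit = 5, min_copies = 3)
  expect_equal(t3$start, 3L)
  expect_equal(t3$end, 14L)
  expect_equal(t3$unit, "ACT")

  expect_equal(nrow(find_exact_tandems("ACGTACGA", max_unit = 2)), 0L)
  # N never matches
  expect_equal(nrow(find_exact_tandems("AANNAA", max_unit = 1,
                                       min_copies = 3)), 0L)
})

test_that("planted perfect arrays are recovered and classified via a .dat fixture", {
  set.seed(21)
  g <- generate_genome(
    c(chrZ = 30000),
    ssr_specs = list(ssr_plant("microsatellite", 3, 60, count = 3),
                     ssr_plant("minisatellite", 20, 55, count = 2),
                     ssr_plant("simple_polyA", 1, 80, count = 2)),
    seed = 33)
  truth <- g$truth
  found <- find_exact_tandems(as.character(g$sequences[[1]]),
                              max_unit = 25, min_copies = 2, seqid = "chrZ")
  # every planted array is present at exactly its planted coordinates
  for (i in seq_along(truth)) {
    hit <- found$start <= GenomicRanges::start(truth)[i] &
      found$end >= GenomicRanges::end(truth)[i]
    expect_true(any(hit))
  }
  # via the .dat dialect: write, re-parse, classify
  dat <- tempfile(fileext = ".dat")
  write_trf_dat(found, dat)
  suppressMessages(back <- classify_arrays(parse_trf_dat(dat)))
  expect_equal(nrow(back), nrow(found))
  # planted classes recovered at planted loci
  for (i in seq_along(truth)) {
    j <- which(back$start <= GenomicRanges::start(truth)[i] &
               back$end >= GenomicRanges::end(truth)[i] &
               back$ssr_class == S4Vectors::mcols(truth)$ssr_class[i])
    expect_true(length(j) >= 1)
  }
})
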