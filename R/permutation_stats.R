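#' Reduced genome sizes for enrichment testing
#'
#' The enrichment null distributes elements over the genome left after
#' removing the bases already covered by the element class under test:
#' `reduced_size(c) = size(c) - covered_bases(c)`.
#'
#' @param chrom_sizes Named vector of chromosome sizes (bp).
#' @param elements `GRanges` of the element class being tested.
#' @return Named numeric vector of reduced sizes (all >= 0).
#' @export
reduced_genome <- function(chrom_sizes, elements) {
  red <- GenomicRanges::reduce(elements, ignore.strand = TRUE)
  cov <- setNames(numeric(length(chrom_sizes)), names(chrom_sizes))
  if (length(red)) {
    tab <- tapply(as.numeric(GenomicRanges::width(red)),
                  as.character(GenomeInfoDb::seqnames(red)), sum)
    cov[names(tab)] <- tab
  }
  out <- as.numeric(chrom_sizes) - cov
  if (any(out < 0)) stop("element coverage exceeds chromosome size")
  setNames(out, names(chrom_sizes))
}

#' Chromosome-level permutation test for element enrichment
#'
#' Tests, per chromosome, whether the observed number of copies (or bp
#' coverage) of a DNA element class is larger or smaller than expected if
#' elements were distributed at random over the reduced genome (see
#' [reduced_genome()]). Each permutation assigns the genome-wide total to
#' chromosomes with probability proportional to reduced size; the
#' empirical 1st and 99th percentiles (at the default `alpha = 0.01`)
#' bound the central 98 % of the null, and a chromosome is called `over`
#' / `under` only when the observation falls strictly outside them.
#'
#' @param observed Named vector: copies per chromosome (`mode = "count"`)
#'   or covered bp per chromosome (`mode = "coverage"`).
#' @param reduced_sizes Named vector from [reduced_genome()].
#' @param n_perm Number of permutations (>= 100; default 100000).
#' @param alpha Tail probability for each side.
#' @param seed Integer seed.
#' @param mode `"count"` or `"coverage"`.
#' @param element_lengths For `mode = "coverage"`: the individual element
#'   lengths (bp) to re-place.
#' @return Data.frame with one row per chromosome: `unit`, `observed`,
#'   `expected`, `low_threshold`, `high_threshold`, `call`, `n_perm`,
#'   `seed`.
#' @export
chromosome_enrichment <- function(observed, reduced_sizes, n_perm = 100000,
                                  alpha = 0.01, seed = 1, mode = "count",
                                  element_lengths = NULL) {
  stopifnot(mode %in% c("count", "coverage"))
  if (n_perm < 100) stop("n_perm must be at least 100 for meaningful ",
                         "percentile thresholds")
  chroms <- names(reduced_sizes)
  if (!all(chroms %in% names(observed))) {
    observed <- setNames(observed[chroms], chroms)
    observed[is.na(observed)] <- 0
  } else {
    observed <- observed[chroms]
  }
  set.seed(seed)
  prob <- reduced_sizes / sum(reduced_sizes)
  if (mode == "count") {
    total <- sum(observed)
    if (total < 1) stop("no elements to permute")
    null <- rmultinom(n_perm, total, prob)       # chrom x n_perm
  } else {
    if (is.null(element_lengths)) {
      stop("element_lengths required in coverage mode")
    }
    total <- length(element_lengths)
    if (total < 1) stop("no elements to permute")
    null <- vapply(seq_len(n_perm), function(i) {
      ch <- sample.int(length(chroms), total, replace = TRUE, prob = prob)
      vapply(seq_along(chroms), function(j)
        sum(element_lengths[ch == j]), numeric(1))
    }, numeric(length(chroms)))
  }
  lo <- apply(null, 1, quantile, probs = alpha, type = 1)
  hi <- apply(null, 1, quantile, probs = 1 - alpha, type = 1)
  call <- ifelse(observed > hi, "over",
                 ifelse(observed < lo, "under", "none"))
  data.frame(unit = chroms, observed = as.numeric(observed),
             expected = as.numeric(rowMeans(null)),
             low_threshold = as.numeric(lo), high_threshold = as.numeric(hi),
             call = call, n_perm = n_perm, seed = seed,
             row.names = NULL)
}

# Place `lens` copy lengths uniformly over the non-N, non-occupied part
# of a chromosome, without overlap, by rejection sampling.
place_copies <- function(lens, chrom_len, n_mask, max_attempts = 1e6) {
  occ <- n_mask                      # logical vector, TRUE = unavailable
  starts <- integer(length(lens))
  attempts <- 0L
  for (i in seq_along(lens)) {
    len <- lens[i]
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("rejection sampling exceeded ", max_attempts,
             " attempts; element coverage too high for non-overlapping ",
             "placement")
      }
      s <- sample.int(chrom_len - len + 1L, 1L)
      if (!any(occ[s:(s + len - 1L)])) break
    }
    occ[s:(s + len - 1L)] <- TRUE
    starts[i] <- s
  }
  starts
}

#' 50-kbp-window permutation scan for TE hotspots
#'
#' Tiles each chromosome with non-overlapping windows (default 50 kbp,
#' starting at position 1; a trailing short window is kept, and windows
#' that are more than half N are excluded from both observed and null
#' tallies). For each chromosome, every permutation re-places the
#' chromosome's TE copies (lengths preserved) uniformly over non-N
#' positions without overlap; per-window copy counts pooled over all
#' permutations and windows of the chromosome form the null, and a window
#' is a hotspot when its observed count strictly exceeds the empirical
#' `1 - alpha` (99th) percentile. A copy is assigned to the window
#' containing its start position.
#'
#' @param te `GRanges` of TE copies.
#' @param chrom_sizes Named vector of chromosome sizes (bp).
#' @param n_runs `GRanges` of N-stretches (may be empty).
#' @param window Window size (bp).
#' @param n_perm Permutations per chromosome (default 1000).
#' @param alpha Upper-tail probability.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap per permutation.
#' @return Data.frame with one row per window: `seqid`, `start`, `end`,
#'   `observed`, `threshold`, `call` (`hotspot`/`none`), `excluded`,
#'   `n_perm`, `seed`.
#' @export
hotspot_scan <- function(te, chrom_sizes, n_runs = GenomicRanges::GRanges(),
                         window = 50000, n_perm = 1000, alpha = 0.01,
                         seed = 1, max_attempts = 1e6) {
  set.seed(seed)
  out <- list()
  te_chr <- as.character(GenomeInfoDb::seqnames(te))
  nr_chr <- as.character(GenomeInfoDb::seqnames(n_runs))
  for (ch in names(chrom_sizes)) {
    L <- as.integer(chrom_sizes[[ch]])
    if (L < window) {
      message("hotspot_scan: ", ch, " shorter than one window; using a ",
              "single truncated window")
    }
    win_starts <- seq(1L, L, by = window)
    win_ends <- pmin(win_starts + window - 1L, L)
    nwin <- length(win_starts)
    # N occupancy
    n_mask <- rep(FALSE, L)
    nr <- n_runs[nr_chr == ch]
    for (i in seq_along(nr)) {
      n_mask[GenomicRanges::start(nr)[i]:GenomicRanges::end(nr)[i]] <- TRUE
    }
    n_frac <- vapply(seq_len(nwin), function(w)
      mean(n_mask[win_starts[w]:win_ends[w]]), numeric(1))
    excluded <- n_frac > 0.5
    copies <- te[te_chr == ch]
    lens <- GenomicRanges::width(copies)
    win_of <- function(starts) pmin((starts - 1L) %/% window + 1L, nwin)
    obs_counts <- tabulate(win_of(GenomicRanges::start(copies)), nwin)
    if (length(copies) == 0L) {
      thr <- 0
      calls <- rep("none", nwin)
    } else {
      null_counts <- integer(0)
      for (p in seq_len(n_perm)) {
        st <- place_copies(lens, L, n_mask, max_attempts)
        cnt <- tabulate(win_of(st), nwin)
        null_counts <- c(null_counts, cnt[!excluded])
      }
      thr <- as.numeric(quantile(null_counts, 1 - alpha, type = 1))
      calls <- ifelse(!excluded & obs_counts > thr, "hotspot", "none")
    }
    out[[ch]] <- data.frame(
      seqid = ch, start = win_starts, end = win_ends,
      observed = obs_counts, threshold = thr, call = calls,
      excluded = excluded, n_perm = n_perm, seed = seed)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
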