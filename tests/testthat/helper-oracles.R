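# Independent per-base bitmap oracle for interval set operations.
# Represents an annotation set as one logical occupancy vector per
# chromosome; deliberately avoids GenomicRanges so it can act as an
# independent check of the interval algebra.

bitmap_new <- function(seq_lengths) {
  lapply(as.list(seq_lengths), function(L) rep(FALSE, L))
}

bitmap_from_df <- function(df, seq_lengths) {
  bm <- bitmap_new(seq_lengths)
  for (i in seq_len(nrow(df))) {
    ch <- as.character(df$seqid[i])
    bm[[ch]][df$start[i]:df$end[i]] <- TRUE
  }
  bm
}

bitmap_from_gr <- function(gr, seq_lengths = GenomeInfoDb::seqlengths(gr)) {
  bitmap_from_df(data.frame(seqid = as.character(GenomeInfoDb::seqnames(gr)),
                            start = GenomicRanges::start(gr),
                            end = GenomicRanges::end(gr)),
                 seq_lengths)
}

bitmap_bases <- function(bm) sum(vapply(bm, sum, numeric(1)))

bitmap_coverage <- function(bm) {
  bitmap_bases(bm) / sum(vapply(bm, length, numeric(1)))
}

bitmap_and <- function(a, b) Map(`&`, a, b)
bitmap_or <- function(a, b) Map(`|`, a, b)
bitmap_diff <- function(a, b) Map(function(x, y) x & !y, a, b)

# Random annotation data.frame on a toy registry.
random_intervals <- function(n, seq_lengths, max_len = 500) {
  ch <- sample(names(seq_lengths), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(seq_lengths[[ch[i]]] - len[i] + 1L, 1L)
  }, integer(1))
  data.frame(seqid = ch, start = start, end = start + len - 1L)
}

# Brute-force stack resolution: pairwise overlap matrix, transitive
# closure into components, then pick the best feature per component by
# (identity, consensus coverage, width, consensus name).
oracle_resolve <- function(df) {
  keep <- integer(0)
  for (ch in unique(df$seqid)) {
    for (mod in unique(df$model)) {
      idx <- which(df$seqid == ch & df$model == mod)
      if (!length(idx)) next
      k <- length(idx)
      adj <- outer(seq_len(k), seq_len(k), function(i, j) {
        df$start[idx[i]] <= df$end[idx[j]] & df$end[idx[i]] >= df$start[idx[j]]
      })
      comp <- seq_len(k)
      repeat {
        changed <- FALSE
        for (i in seq_len(k)) for (j in seq_len(k)) {
          if (adj[i, j] && comp[j] != comp[i]) {
            comp[comp == comp[j]] <- comp[i]; changed <- TRUE
          }
        }
        if (!changed) break
      }
      for (cc in unique(comp)) {
        ii <- idx[comp == cc]
        o <- order(-df$identity[ii], -df$consensus_coverage[ii],
                   -(df$end[ii] - df$start[ii]), df$consensus[ii],
                   method = "radix")
        keep <- c(keep, ii[o[1]])
      }
    }
  }
  sort(keep)
}

# A genome with one planted TE model, reused by DM and pipeline tests.
make_te_genome <- function(chrom = c(chrA = 120000), n_copies = 20,
                           divergence = c(0.1, 0.15), consensus_len = 1000,
                           seed = 101, ...) {
  set.seed(seed)
  cons <- paste(sample(c("A", "C", "G", "T"), consensus_len, TRUE),
                collapse = "")
  generate_genome(
    chrom,
    te_specs = list(repeat_model("TEx", cons, "LINE", copy_count = n_copies,
                                 divergence_range = divergence, ...)),
    seed = seed)
}
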