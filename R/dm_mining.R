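#' Select well-conserved TE copies as dark-matter probes
#'
#' Dark matter (DM) mining re-annotates a genome with its own
#' best-conserved repeat copies to recover older, more divergent
#' segments. Probes are the annotated copies strictly longer than
#' `min_len` bp (default 500) with identity to their consensus of at
#' least `min_identity` (default 0.80). Copies lacking an identity
#' attribute are excluded with a message.
#'
#' @param annotations Annotation set with `model` and `identity`
#'   (fraction) columns, optionally `consensus`.
#' @param genome [Biostrings::DNAStringSet] to extract probe sequences
#'   from.
#' @param min_len Probe length must be strictly greater (bp).
#' @param min_identity Minimum identity to the consensus (fraction).
#' @return Data.frame with `model`, `consensus`, `seqid`, `start`, `end`,
#'   `length`, `identity`, `sequence`.
#' @export
select_probes <- function(annotations, genome, min_len = 500,
                          min_identity = 0.80) {
  mc <- S4Vectors::mcols(annotations)
  ident <- mc$identity
  if (is.null(ident)) ident <- rep(NA_real_, length(annotations))
  nmiss <- sum(is.na(ident))
  if (nmiss > 0) message("select_probes: excluded ", nmiss,
                         " copy(ies) missing the identity attribute")
  keep <- which(!is.na(ident) &
                GenomicRanges::width(annotations) > min_len &
                ident >= min_identity)
  if (!length(keep)) {
    return(data.frame(model = character(), consensus = character(),
                      seqid = character(), start = integer(),
                      end = integer(), length = integer(),
                      identity = numeric(), sequence = character()))
  }
  sub <- annotations[keep]
  seqv <- vapply(seq_along(sub), function(i) {
    as.character(Biostrings::subseq(
      genome[[as.character(GenomeInfoDb::seqnames(sub)[i])]],
      GenomicRanges::start(sub)[i], GenomicRanges::end(sub)[i]))
  }, character(1))
  data.frame(
    model = as.character(S4Vectors::mcols(sub)$model),
    consensus = as.character(S4Vectors::mcols(sub)$consensus %||%
                               rep(NA_character_, length(sub))),
    seqid = as.character(GenomeInfoDb::seqnames(sub)),
    start = GenomicRanges::start(sub), end = GenomicRanges::end(sub),
    length = GenomicRanges::width(sub),
    identity = ident[keep], sequence = seqv
  )
}

# Ungapped X-drop extension of one seeded diagonal.
# probe_chars / subj_chars are the aligned character vectors of equal
# length along the diagonal; seed_start/seed_end index into them.
extend_diagonal <- function(match_vec, seed_start, seed_end, x_drop) {
  score <- ifelse(match_vec, 1, -1)
  n <- length(score)
  # right extension
  right_end <- seed_end
  if (seed_end < n) {
    cs <- cumsum(score[(seed_end + 1L):n])
    drop_at <- which(cummax(cs) - cs > x_drop)
    lim <- if (length(drop_at)) drop_at[1] - 1L else length(cs)
    if (lim > 0) {
      best <- which.max(cs[seq_len(lim)])
      if (cs[best] > 0) right_end <- seed_end + best
    }
  }
  # left extension
  left_start <- seed_start
  if (seed_start > 1L) {
    cs <- cumsum(score[(seed_start - 1L):1L])
    drop_at <- which(cummax(cs) - cs > x_drop)
    lim <- if (length(drop_at)) drop_at[1] - 1L else length(cs)
    if (lim > 0) {
      best <- which.max(cs[seq_len(lim)])
      if (cs[best] > 0) left_start <- seed_start - best
    }
  }
  c(left_start, right_end)
}

# One-off seed index of a chromosome: k-mer string -> start positions.
build_seed_index <- function(subject_chars, seed_k) {
  L <- length(subject_chars)
  if (L < seed_k) return(list())
  n <- L - seed_k + 1L
  s <- paste(subject_chars, collapse = "")
  gk <- substring(s, seq_len(n), seq_len(n) + seed_k - 1L)
  keep <- !grepl("N", gk, fixed = TRUE)
  split(which(keep), gk[keep])
}

scan_one_strand <- function(probe_seq, subject_chars, seed_index, seqid,
                            strand, seed_k, min_hit_identity, min_hit_len,
                            x_drop) {
  plen <- nchar(probe_seq)
  slen <- length(subject_chars)
  if (plen < seed_k || !length(seed_index)) return(NULL)
  n <- plen - seed_k + 1L
  pk <- substring(probe_seq, seq_len(n), seq_len(n) + seed_k - 1L)
  clean <- !grepl("N", pk, fixed = TRUE)
  pos_lists <- seed_index[pk[clean]]
  found <- !vapply(pos_lists, is.null, logical(1))
  offsets <- which(clean)[found]
  pos_lists <- pos_lists[found]
  if (!length(offsets)) return(NULL)
  p_off <- rep(offsets, lengths(pos_lists))
  s_pos <- unlist(pos_lists, use.names = FALSE)
  dgs <- s_pos - p_off
  ord <- order(dgs, p_off)
  p_off <- p_off[ord]; dgs <- dgs[ord]
  pr_chr <- chars(probe_seq)
  out <- list()
  for (grp in split(seq_along(dgs), dgs)) {
    dg <- dgs[grp[1]]
    # full overlap of the probe with the subject along this diagonal
    p_lo <- max(1L, 1L - dg)
    p_hi <- min(plen, slen - dg)
    if (p_hi - p_lo + 1L < min_hit_len) next
    pr <- pr_chr[p_lo:p_hi]
    sb <- subject_chars[(p_lo + dg):(p_hi + dg)]
    mv <- pr == sb & pr != "N" & sb != "N"
    covered_to <- 0L
    for (off in p_off[grp]) {
      s0 <- off - p_lo + 1L
      s1 <- s0 + seed_k - 1L
      if (s1 <= covered_to) next
      ext <- extend_diagonal(mv, s0, s1, x_drop)
      covered_to <- ext[2]
      len <- ext[2] - ext[1] + 1L
      ident <- mean(mv[ext[1]:ext[2]])
      if (len < min_hit_len || ident < min_hit_identity) next
      g0 <- p_lo + dg + ext[1] - 1L
      g1 <- p_lo + dg + ext[2] - 1L
      out[[length(out) + 1L]] <- data.frame(
        seqid = seqid, start = g0, end = g1, strand = strand,
        identity = ident, length = len)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Seed-and-extend homology scan with a probe library
#'
#' Re-annotates a genome by exact `seed_k`-mer seeding (both strands)
#' followed by ungapped X-drop extension (+1 match / -1 mismatch, drop
#' `x_drop`). A hit is reported when it reaches `min_hit_len` bp at
#' identity `min_hit_identity`; it inherits the probe's TE model.
#' Substitution-level divergence is handled; indel-containing copies
#' fragment into several hits.
#'
#' @param probes Probe table from [select_probes()] (needs `model`,
#'   `sequence`; `consensus` optional).
#' @param genome [Biostrings::DNAStringSet].
#' @param seed_k Exact seed length (bp).
#' @param min_hit_identity Minimum hit identity (fraction).
#' @param min_hit_len Minimum hit length (bp).
#' @param x_drop X-drop termination threshold (score units).
#' @return Registered `GRanges` of hits with `model`, `probe`,
#'   `identity` columns.
#' @export
homology_scan <- function(probes, genome, seed_k = 11,
                          min_hit_identity = 0.60, min_hit_len = 20,
                          x_drop = 20) {
  stopifnot(nrow(probes) > 0)
  rows <- list()
  for (ch in names(genome)) {
    subject_chars <- chars(as.character(genome[[ch]]))
    seed_index <- build_seed_index(subject_chars, seed_k)
    for (pi in seq_len(nrow(probes))) {
      for (std in c("+", "-")) {
        pseq <- if (std == "+") probes$sequence[pi]
                else revcomp_chr(probes$sequence[pi])
        r <- scan_one_strand(pseq, subject_chars, seed_index, ch, std,
                             seed_k, min_hit_identity, min_hit_len, x_drop)
        if (!is.null(r)) {
          r$model <- probes$model[pi]
          r$probe <- sprintf("probe_%04d", pi)
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  sl <- setNames(Biostrings::width(genome), names(genome))
  if (is.null(df)) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    return(gr)
  }
  gr <- GenomicRanges::GRanges(df$seqid, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    model = df$model, probe = df$probe, identity = df$identity)
  annotation_set(sort(gr), sl)
}

#' Subtract known annotations from DM hits
#'
#' Removes every base already covered by the known (SSR + TE) annotation
#' from the dark-matter hits; hits may be split across subtracted spans.
#' The result has zero base-level overlap with `known`.
#'
#' @param hits DM hit set (e.g. from [homology_scan()]).
#' @param known Annotation set of already-identified repeats.
#' @return The subtracted `GRanges`, attributes preserved.
#' @export
subtract_known <- function(hits, known) {
  subtract_annotations(hits, known)
}

#' Classify DM segments as new or extending
#'
#' A DM segment lying within `adjacency_gap` bp of an existing annotation
#' of the SAME TE model extends that annotation (`dm_status =
#' "extended"`); all others are `"new"`. With the default gap of 0 only
#' abutting (or overlapping) segments count as extensions.
#'
#' @param dm DM annotation set with a `model` column.
#' @param existing Existing annotation set with a `model` column.
#' @param adjacency_gap Maximum gap (bp) for "extended".
#' @return `dm` with a `dm_status` column.
#' @export
classify_dm <- function(dm, existing, adjacency_gap = 0) {
  status <- rep("new", length(dm))
  exist_model <- as.character(S4Vectors::mcols(existing)$model)
  dm_model <- as.character(S4Vectors::mcols(dm)$model)
  for (mod in unique(dm_model)) {
    ex <- existing[exist_model == mod]
    if (!length(ex)) next
    qi <- which(dm_model == mod)
    d <- GenomicRanges::distanceToNearest(dm[qi], ex, ignore.strand = TRUE)
    hit <- S4Vectors::queryHits(d)[S4Vectors::mcols(d)$distance <=
                                     adjacency_gap]
    status[qi[hit]] <- "extended"
  }
  S4Vectors::mcols(dm)$dm_status <- status
  dm
}
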