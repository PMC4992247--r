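#' N-run index for strip/restore coordinate remapping
#'
#' Assembly gaps are stored as runs of `N`. Some scanning tools mishandle
#' them (e.g. treat them as `A` stretches), so the gaps are removed before
#' scanning and every reported interval is lifted back to original
#' coordinates afterwards. An `n_index` records, for one sequence, the
#' maximal N-runs in original coordinates together with the original and
#' stripped lengths; it is the complete information needed for the lift.
#'
#' All coordinates are 1-based inclusive (the GFF3/IRanges convention);
#' BED serialisation converts to 0-based half-open at the boundary.
#'
#' @param runs An [IRanges::IRanges] of maximal N-runs in original
#'   coordinates (sorted, non-overlapping).
#' @param original_length Original sequence length in bp.
#' @return An object of class `n_index`.
#' @seealso [strip_n()], [restore_interval()]
#' @export
n_index <- function(runs, original_length) {
  runs <- IRanges::reduce(runs)
  stripped <- original_length - sum(IRanges::width(runs))
  structure(
    list(runs = runs, original_length = as.integer(original_length),
         stripped_length = as.integer(stripped)),
    class = "n_index"
  )
}

#' @export
print.n_index <- function(x, ...) {
  cat(sprintf("n_index: %d N-run(s), original %d bp, stripped %d bp\n",
              length(x$runs), x$original_length, x$stripped_length))
  invisible(x)
}

#' Strip N-runs from a sequence
#'
#' Removes every run of `N`/`n` from a nucleotide sequence and returns the
#' stripped sequence together with the [n_index()] needed to restore
#' coordinates. Soft-masked (lower-case) non-N bases are preserved
#' verbatim. An empty sequence yields an empty index and empty output.
#'
#' @param sequence A character scalar, [Biostrings::DNAString] or
#'   [Biostrings::BString] over `A,C,G,T,N` (case-insensitive).
#' @return A list with elements `sequence` (character, no Ns) and
#'   `index` (an `n_index`).
#' @examples
#' strip_n("ACNNGT")$sequence   # "ACGT"
#' @export
strip_n <- function(sequence) {
  sequence <- as.character(sequence)
  len <- nchar(sequence)
  if (len == 0L) {
    return(list(sequence = "",
                index = n_index(IRanges::IRanges(), 0L)))
  }
  m <- gregexpr("[Nn]+", sequence)[[1]]
  if (m[1] == -1L) {
    runs <- IRanges::IRanges()
  } else {
    runs <- IRanges::IRanges(start = as.integer(m),
                             width = attr(m, "match.length"))
  }
  stripped <- gsub("[Nn]", "", sequence)
  list(sequence = stripped, index = n_index(runs, len))
}

# Kept (non-N) segments of an index, with their stripped-coordinate spans.
kept_segments <- function(index) {
  keep <- IRanges::setdiff(IRanges::IRanges(1L, index$original_length),
                           index$runs)
  w <- IRanges::width(keep)
  se <- cumsum(w)
  data.frame(
    orig_start = IRanges::start(keep), orig_end = IRanges::end(keep),
    strip_start = se - w + 1L, strip_end = se
  )
}

#' Restore a stripped-coordinate interval to original coordinates
#'
#' Maps an interval expressed in stripped (N-free) coordinates back to the
#' original sequence. An interval spanning one or more removed N-runs is
#' split into the corresponding original-coordinate pieces; the pieces
#' share one `part` identifier series (1, 2, ...). Annotations are split
#' rather than extended across a gap because the gap bases were never
#' scored by the wrapped tool.
#'
#' @param index An [n_index()].
#' @param start,end Interval bounds in stripped coordinates (1-based
#'   inclusive); vectors are recycled pairwise.
#' @return A data.frame with columns `query` (input row), `part`,
#'   `start`, `end` in original coordinates.
#' @examples
#' idx <- strip_n("ACNNGT")$index
#' restore_interval(idx, 3, 4)  # original [5, 6]
#' @export
restore_interval <- function(index, start, end) {
  stopifnot(inherits(index, "n_index"))
  n <- max(length(start), length(end))
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (any(start < 1L) || any(end > index$stripped_length) ||
      any(end < start)) {
    stop("interval out of range of the stripped sequence (length ",
         index$stripped_length, ")")
  }
  segs <- kept_segments(index)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- which(segs$strip_end >= start[i] & segs$strip_start <= end[i])
    os <- segs$orig_start[hit] + pmax(start[i] - segs$strip_start[hit], 0L)
    oe <- segs$orig_end[hit] - pmax(segs$strip_end[hit] - end[i], 0L)
    out[[i]] <- data.frame(query = i, part = seq_along(hit),
                           start = os, end = oe)
  }
  do.call(rbind, out)
}

#' Restore stripped-coordinate annotations on multiple sequences
#'
#' Applies [restore_interval()] to every feature of a `GRanges` whose
#' coordinates refer to N-stripped sequences. Features spanning a removed
#' N-run come back as several ranges sharing the original feature's
#' attributes plus a `part` column.
#'
#' @param gr A [GenomicRanges::GRanges] in stripped coordinates.
#' @param indices Named list of [n_index()] objects, one per seqid in `gr`.
#' @return A `GRanges` in original coordinates with seqlengths set to the
#'   original sequence lengths.
#' @export
restore_annotations <- function(gr, indices) {
  missing <- setdiff(as.character(unique(GenomeInfoDb::seqnames(gr))),
                     names(indices))
  if (length(missing)) {
    stop("no n_index for sequence(s): ", paste(missing, collapse = ", "))
  }
  pieces <- lapply(seq_along(gr), function(i) {
    sq <- as.character(GenomeInfoDb::seqnames(gr)[i])
    res <- restore_interval(indices[[sq]],
                            GenomicRanges::start(gr)[i],
                            GenomicRanges::end(gr)[i])
    out <- GenomicRanges::GRanges(
      sq, IRanges::IRanges(res$start, res$end),
      strand = GenomicRanges::strand(gr)[i],
      seqlengths = vapply(indices, function(ix) {
        ix$original_length
      }, integer(1))
    )
    mc <- S4Vectors::mcols(gr)[rep(i, nrow(res)), , drop = FALSE]
    mc$part <- res$part
    S4Vectors::mcols(out) <- mc
    out
  })
  out <- if (length(pieces)) do.call(c, pieces) else
    GenomicRanges::GRanges()
  lens <- vapply(indices, function(ix) ix$original_length, integer(1))
  GenomeInfoDb::seqlevels(out) <- names(indices)
  GenomeInfoDb::seqlengths(out) <- lens
  out
}

#' Serialise an N-run index as BED
#'
#' BED uses 0-based half-open coordinates; conversion happens here, at the
#' I/O boundary only.
#'
#' @param indices Named list of [n_index()] objects.
#' @param path Output file.
#' @export
write_n_index_bed <- function(indices, path) {
  rows <- lapply(names(indices), function(nm) {
    r <- indices[[nm]]$runs
    if (!length(r)) return(NULL)
    data.frame(chrom = nm, start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer())
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an N-run index from BED
#'
#' @param path BED file of N-runs (0-based half-open).
#' @param seq_lengths Named integer vector of original sequence lengths.
#' @return Named list of [n_index()] objects (one per entry of
#'   `seq_lengths`, empty where the BED has no runs).
#' @export
read_n_index_bed <- function(path, seq_lengths) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", col.names = c("chrom", "start", "end"),
                      colClasses = c("character", "integer", "integer")),
    error = function(e) data.frame(chrom = character(), start = integer(),
                                   end = integer())
  )
  setNames(lapply(names(seq_lengths), function(nm) {
    sub <- df[df$chrom == nm, , drop = FALSE]
    n_index(IRanges::IRanges(sub$start + 1L, sub$end), seq_lengths[[nm]])
  }), names(seq_lengths))
}
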