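#' Build an annotation set
#'
#' An annotation set is a [GenomicRanges::GRanges] whose `seqinfo` carries
#' the genome size registry: every seqid in use must have a registered
#' length, because coverage denominators are full registered sequence
#' lengths (including N bases). Coordinates are 1-based inclusive.
#'
#' @param gr A `GRanges`, or a data.frame with `seqid`, `start`, `end`
#'   columns (extra columns become metadata).
#' @param seq_lengths Named vector of sequence lengths (the registry).
#' @return A `GRanges` with seqlengths set.
#' @export
annotation_set <- function(gr, seq_lengths) {
  if (is.data.frame(gr)) {
    mc <- gr[, setdiff(names(gr), c("seqid", "start", "end", "strand")),
             drop = FALSE]
    gr2 <- GenomicRanges::GRanges(
      gr$seqid, IRanges::IRanges(gr$start, gr$end),
      strand = if (!is.null(gr$strand)) gr$strand else
        rep("*", nrow(gr))
    )
    S4Vectors::mcols(gr2) <- S4Vectors::DataFrame(mc)
    gr <- gr2
  }
  used <- as.character(unique(GenomeInfoDb::seqnames(gr)))
  unreg <- setdiff(used, names(seq_lengths))
  if (length(unreg)) {
    stop("unregistered seqid(s): ", paste(unreg, collapse = ", "))
  }
  GenomeInfoDb::seqlevels(gr) <- names(seq_lengths)
  GenomeInfoDb::seqlengths(gr) <- seq_lengths
  gr
}

registry_size <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) {
    stop("annotation set has unregistered sequence lengths; ",
         "use annotation_set() to attach the genome registry")
  }
  sum(as.numeric(sl))
}

#' Read / write GFF3 annotations
#'
#' Thin wrappers around [rtracklayer::import.gff3()] /
#' [rtracklayer::export.gff3()] that attach the genome registry.
#'
#' @param path GFF3 file.
#' @param seq_lengths Named vector of sequence lengths.
#' @return `read_gff3_annotations`: a registered `GRanges`.
#' @export
read_gff3_annotations <- function(path, seq_lengths = NULL) {
  gr <- rtracklayer::import.gff3(path)
  if (!is.null(seq_lengths)) gr <- annotation_set(gr, seq_lengths)
  gr
}

#' @rdname read_gff3_annotations
#' @param gr A `GRanges` to write.
#' @export
write_gff3_annotations <- function(gr, path) {
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

# Connected overlap components within one (seqid, model) group.
overlap_components <- function(gr) {
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
}

#' Resolve stacked annotations
#'
#' Among mutually overlapping features of the same TE model (annotations
#' of one copy produced by several consensuses of that model), keeps one
#' representative per stack, chosen by (1) highest percent identity to its
#' consensus, (2) highest fraction of the consensus covered, ties broken
#' by longer interval then lexicographically smaller consensus name. The
#' output has no same-model overlaps. Features missing the identity
#' attribute are treated as identity 0 and reported with a message.
#'
#' @param gr Annotation set with metadata columns `model`, `identity`
#'   (percent or fraction, any consistent scale), and optionally
#'   `consensus_coverage` and `consensus`.
#' @return The resolved `GRanges`.
#' @export
resolve_stacks <- function(gr) {
  if (!length(gr)) return(gr)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$model)) stop("features must carry a 'model' attribute")
  ident <- mc$identity
  if (is.null(ident)) ident <- rep(NA_real_, length(gr))
  nmiss <- sum(is.na(ident))
  if (nmiss > 0) {
    message("resolve_stacks: ", nmiss,
            " feature(s) missing identity; treated as 0")
    ident[is.na(ident)] <- 0
  }
  ccov <- mc$consensus_coverage %||% rep(0, length(gr))
  ccov[is.na(ccov)] <- 0
  cons <- as.character(mc$consensus %||% rep("", length(gr)))
  key <- paste(GenomeInfoDb::seqnames(gr), mc$model, sep = "\r")
  keep <- unlist(lapply(split(seq_along(gr), key), function(idx) {
    comp <- overlap_components(gr[idx])
    vapply(split(idx, comp), function(ii) {
      o <- order(-ident[ii], -ccov[ii],
                 -GenomicRanges::width(gr[ii]),
                 cons[ii], method = "radix")
      ii[o[1]]
    }, integer(1))
  }), use.names = FALSE)
  sort(gr[sort(keep)])
}

#' Merge juxtaposed annotations
#'
#' Fuses same-model features separated by at most `max_gap` bp into one
#' feature spanning both; the fused feature records the constituent
#' consensus names (comma-joined, in genomic order) and a width-weighted
#' mean identity. Stacks should be resolved first.
#'
#' @param gr Annotation set with a `model` column.
#' @param max_gap Largest gap (bp) across which two features fuse;
#'   0 means bookended features only.
#' @return The merged `GRanges`.
#' @export
merge_juxtaposed <- function(gr, max_gap = 0) {
  if (!length(gr)) return(gr)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$model)) stop("features must carry a 'model' attribute")
  cons <- as.character(mc$consensus %||% rep(NA_character_, length(gr)))
  ident <- mc$identity %||% rep(NA_real_, length(gr))
  key <- paste(GenomeInfoDb::seqnames(gr), mc$model, sep = "\r")
  pieces <- lapply(split(seq_along(gr), key), function(idx) {
    sub <- gr[idx]
    red <- GenomicRanges::reduce(sub, min.gapwidth = max_gap + 1,
                                 ignore.strand = TRUE, with.revmap = TRUE)
    rm <- S4Vectors::mcols(red)$revmap
    ord <- order(GenomicRanges::start(sub))
    S4Vectors::mcols(red) <- S4Vectors::DataFrame(
      model = S4Vectors::mcols(sub)$model[1],
      consensus = vapply(rm, function(ii) {
        cc <- cons[idx][ii][order(GenomicRanges::start(sub)[ii])]
        paste(unique(cc[!is.na(cc)]), collapse = ",")
      }, character(1)),
      identity = vapply(rm, function(ii) {
        w <- GenomicRanges::width(sub)[ii]
        stats::weighted.mean(ident[idx][ii], w, na.rm = TRUE)
      }, numeric(1)),
      n_merged = lengths(rm)
    )
    red
  })
  out <- sort(do.call(c, unname(pieces)))
  out
}

#' Count TE copies with long-join resolution
#'
#' A TE copy interrupted by a nested insertion of a different model is
#' annotated as two same-model fragments flanking the guest. Long-join
#' counting treats such fragment pairs as ONE copy: consecutive
#' same-model fragments are joined when the intervening gap is entirely
#' covered by features of other models (the nested insertion) and the
#' gap is at most `max_nested_span` bp. Intervals remain split; only the copy count and
#' copy identifiers change.
#'
#' @param gr Merged annotation set with a `model` column.
#' @param max_nested_span Largest nested-insertion span (bp) across which
#'   two fragments still count as one copy.
#' @return A list with `features` (input `GRanges` plus a `copy_id`
#'   column) and `copies` (data.frame: `model`, `seqid`, `copy_id`,
#'   `n_fragments`, `total_length`).
#' @export
long_join_copies <- function(gr, max_nested_span = 10000) {
  if (!length(gr)) {
    return(list(features = gr,
                copies = data.frame(model = character(), seqid = character(),
                                    copy_id = character(),
                                    n_fragments = integer(),
                                    total_length = integer())))
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$model)) stop("features must carry a 'model' attribute")
  copy_id <- character(length(gr))
  key <- paste(GenomeInfoDb::seqnames(gr), mc$model, sep = "\r")
  counter <- 0L
  for (idx in split(seq_along(gr), key)) {
    idx <- idx[order(GenomicRanges::start(gr)[idx])]
    grp <- integer(length(idx))
    grp[1] <- 1L
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        gap_s <- GenomicRanges::end(gr)[idx[j - 1]] + 1L
        gap_e <- GenomicRanges::start(gr)[idx[j]] - 1L
        joined <- FALSE
        if (gap_e >= gap_s && (gap_e - gap_s + 1L) <= max_nested_span) {
          gap <- GenomicRanges::GRanges(
            GenomeInfoDb::seqnames(gr)[idx[j]],
            IRanges::IRanges(gap_s, gap_e))
          other <- gr[as.character(GenomeInfoDb::seqnames(gr)) ==
                        as.character(GenomeInfoDb::seqnames(gr)[idx[j]]) &
                      mc$model != mc$model[idx[j]]]
          # the fragments must flank the insertion: the whole gap is
          # occupied by features of other models
          if (length(other)) {
            covered <- sum(GenomicRanges::width(GenomicRanges::intersect(
              GenomicRanges::reduce(other, ignore.strand = TRUE), gap,
              ignore.strand = TRUE)))
            joined <- covered == (gap_e - gap_s + 1L)
          }
        }
        grp[j] <- if (joined) grp[j - 1] else grp[j - 1] + 1L
      }
    }
    copy_id[idx] <- sprintf("copy_%06d", counter + grp)
    counter <- counter + max(grp)
  }
  out <- gr
  S4Vectors::mcols(out)$copy_id <- copy_id
  copies <- do.call(rbind, lapply(split(seq_along(out), copy_id), function(ii) {
    data.frame(
      model = as.character(mc$model[ii[1]]),
      seqid = as.character(GenomeInfoDb::seqnames(out)[ii[1]]),
      copy_id = copy_id[ii[1]],
      n_fragments = length(ii),
      total_length = sum(GenomicRanges::width(out)[ii])
    )
  }))
  rownames(copies) <- NULL
  list(features = out, copies = copies)
}

#' Filter annotations by minimum length
#'
#' Drops features shorter than `min_len` bp (default 20 bp, the minimum
#' TE copy size used for the final annotation); the number removed is
#' reported with a message.
#'
#' @param gr Annotation set.
#' @param min_len Minimum feature length (bp) to keep.
#' @return The filtered `GRanges`.
#' @export
filter_min_length <- function(gr, min_len = 20) {
  drop <- GenomicRanges::width(gr) < min_len
  if (any(drop)) message("filter_min_length: removed ", sum(drop),
                         " feature(s) < ", min_len, " bp")
  gr[!drop]
}

#' Base-level set operations on annotation sets
#'
#' `intersect_annotations` and `subtract_annotations` have base-level
#' (per-nucleotide) semantics, ignoring strand; `subtract_annotations`
#' keeps each surviving piece's original attributes (plus a `part`
#' counter when a feature is split). `union_coverage` is the fraction of
#' the registered genome covered by the union of the given sets.
#'
#' @param a,b Registered annotation sets (see [annotation_set()]).
#' @param ... For `union_coverage`: one or more annotation sets.
#' @return `GRanges` (collapsed for intersect; attribute-carrying pieces
#'   for subtract) or a coverage fraction.
#' @export
intersect_annotations <- function(a, b) {
  GenomicRanges::intersect(GenomicRanges::reduce(a, ignore.strand = TRUE),
                           GenomicRanges::reduce(b, ignore.strand = TRUE),
                           ignore.strand = TRUE)
}

#' @rdname intersect_annotations
#' @export
subtract_annotations <- function(a, b) {
  if (!length(a)) return(a)
  bred <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  pieces <- lapply(seq_along(a), function(i) {
    left <- GenomicRanges::setdiff(a[i], bred, ignore.strand = TRUE)
    if (!length(left)) return(NULL)
    mc <- S4Vectors::mcols(a)[rep(i, length(left)), , drop = FALSE]
    if (length(left) > 1) mc$part <- seq_along(left)
    S4Vectors::mcols(left) <- mc
    GenomicRanges::strand(left) <- GenomicRanges::strand(a)[i]
    left
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    out <- a[0]
  } else {
    out <- suppressWarnings(do.call(c, pieces))
  }
  out
}

#' @rdname intersect_annotations
#' @export
union_coverage <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0)
  un <- GenomicRanges::reduce(
    do.call(c, lapply(sets, function(g) GenomicRanges::granges(g))),
    ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(un))) / registry_size(sets[[1]])
}

#' Coverage fraction of one annotation set
#'
#' Covered bases (union of intervals) divided by the registered genome
#' size. The denominator includes N bases; pass `exclude` (e.g. the
#' N-run set) to remove bases from the denominator.
#'
#' @param gr Registered annotation set.
#' @param exclude Optional `GRanges` of bases to drop from the
#'   denominator.
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(gr, exclude = NULL) {
  denom <- registry_size(gr)
  if (!is.null(exclude)) {
    denom <- denom -
      sum(as.numeric(GenomicRanges::width(
        GenomicRanges::reduce(exclude, ignore.strand = TRUE))))
  }
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(gr, ignore.strand = TRUE)))) / denom
}

#' Venn-diagram coverage of named annotation sets
#'
#' Partitions the union of the given sets into disjoint regions by
#' membership combination and reports the coverage fraction of each
#' non-empty combination. Region coverages sum to the union coverage.
#'
#' @param sets Named list of registered annotation sets.
#' @return Data.frame with `members` (comma-joined set names) and
#'   `coverage` (fraction of the registered genome).
#' @export
venn_coverage <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  gsize <- registry_size(sets[[1]])
  red <- lapply(sets, function(g) GenomicRanges::reduce(g, ignore.strand = TRUE))
  all_gr <- do.call(c, unname(lapply(red, function(g)
    GenomicRanges::granges(g))))
  if (!length(all_gr)) {
    return(data.frame(members = character(), coverage = numeric()))
  }
  dj <- GenomicRanges::disjoin(all_gr, ignore.strand = TRUE)
  member <- vapply(red, function(g)
    IRanges::overlapsAny(dj, g, ignore.strand = TRUE),
    logical(length(dj)))
  member <- matrix(member, nrow = length(dj))
  labels <- apply(member, 1, function(m)
    paste(names(sets)[m], collapse = ","))
  w <- as.numeric(GenomicRanges::width(dj))
  agg <- tapply(w, labels, sum)
  out <- data.frame(members = names(agg),
                    coverage = as.numeric(agg) / gsize,
                    row.names = NULL)
  out[order(-out$coverage), , drop = FALSE]
}
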