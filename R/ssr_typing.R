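#' Parse Tandem Repeats Finder `.dat` output
#'
#' Reads the `.dat` dialect produced by `trf <fasta> 2 5 7 80 10 25 2000 -d`:
#' `Sequence:` header lines followed by whitespace-separated 15-field
#' detection records. Records inherit the seqid of the preceding header.
#' Unknown header lines (program banner, `Parameters:` ...) are skipped
#' with a message; a numeric-looking line with the wrong field count is an
#' error naming the line number.
#'
#' @param path Path to a `.dat` file, or a character vector of lines.
#' @return A data.frame of tandem arrays with columns `seqid`, `start`,
#'   `end` (1-based inclusive, as printed), `unit_length`, `copy_number`
#'   (possibly fractional), `consensus_size`, `percent_matches`,
#'   `percent_indels`, `score`, `unit` (consensus repeat unit) and
#'   `sequence` (the detected array).
#' @export
parse_trf_dat <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  seqid <- NA_character_
  rows <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^Sequence:", ln)) {
      seqid <- trimws(sub("^Sequence:\\s*", "", ln))
      seqid <- strsplit(seqid, "\\s+")[[1]][1]
      next
    }
    if (!grepl("^[0-9]", ln)) {  # banner / Parameters: / version lines
      skipped <- skipped + 1L
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 15L) {
      stop("malformed TRF record at line ", i, ": expected 15 fields, got ",
           length(f))
    }
    if (is.na(seqid)) {
      stop("TRF record at line ", i, " appears before any 'Sequence:' header")
    }
    rows[[i]] <- data.frame(
      seqid = seqid,
      start = as.integer(f[1]), end = as.integer(f[2]),
      unit_length = as.integer(f[3]), copy_number = as.numeric(f[4]),
      consensus_size = as.integer(f[5]),
      percent_matches = as.numeric(f[6]), percent_indels = as.numeric(f[7]),
      score = as.numeric(f[8]),
      unit = f[14], sequence = f[15]
    )
  }
  if (skipped > 0L) message("parse_trf_dat: skipped ", skipped,
                            " non-record header line(s)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(seqid = character(), start = integer(), end = integer(),
                      unit_length = integer(), copy_number = numeric(),
                      consensus_size = integer(), percent_matches = numeric(),
                      percent_indels = numeric(), score = numeric(),
                      unit = character(), sequence = character())
  }
  rownames(out) <- NULL
  out
}

#' Write tandem arrays in the TRF `.dat` dialect
#'
#' Inverse of [parse_trf_dat()]; mainly useful for building fixtures from
#' the exact-tandem oracle.
#'
#' @param arrays A data.frame as returned by [parse_trf_dat()] or
#'   [find_exact_tandems()].
#' @param path Output file.
#' @export
write_trf_dat <- function(arrays, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sq in unique(arrays$seqid)) {
    writeLines(paste("Sequence:", sq), con)
    writeLines("", con)
    sub <- arrays[arrays$seqid == sq, , drop = FALSE]
    comp <- function(s, b) {
      round(100 * vapply(strsplit(s, ""), function(x) mean(x == b), 0))
    }
    writeLines(sprintf("%d %d %d %.1f %d %d %d %d %d %d %d %d %.2f %s %s",
                       sub$start, sub$end, sub$unit_length, sub$copy_number,
                       sub$consensus_size %||% sub$unit_length,
                       sub$percent_matches %||% 100, sub$percent_indels %||% 0,
                       sub$score %||% 2 * nchar(sub$sequence),
                       comp(sub$sequence, "A"), comp(sub$sequence, "C"),
                       comp(sub$sequence, "G"), comp(sub$sequence, "T"),
                       1.5, sub$unit, sub$sequence), con)
  }
  invisible(path)
}

#' Classify a tandem array into the SSR taxonomy
#'
#' Applies the unit-length taxonomy and copy-number retention rules used
#' for the genome-wide SSR census:
#' \itemize{
#'   \item unit 1 bp: simple repeat, sub-typed `simple_polyA` if the unit
#'     is A/T, `simple_polyC` if C/G;
#'   \item unit 2--10 bp: `microsatellite`;
#'   \item unit 11--60 bp: `minisatellite`;
#'   \item the three classes above are retained only with at least
#'     `min_units_small` (default 50) repeat units, otherwise `rejected`;
#'   \item unit > 60 bp with 2 to `satellite_min_units` copies:
#'     `large_tandem_repeat`; with more than `satellite_min_units` copies:
#'     `satellite`.
#' }
#' Fractional copy numbers (as reported by TRF) are compared directly to
#' the thresholds (`>= 50` retains; `> 50` promotes to satellite).
#'
#' @param unit_length Repeat-unit length(s) in bp.
#' @param copy_number Number of repeat units (possibly fractional).
#' @param unit Consensus repeat unit sequence(s); needed only for 1-bp
#'   units (polyA/polyC sub-typing).
#' @param min_units_small Minimum repeat units to retain a simple repeat,
#'   microsatellite or minisatellite.
#' @param unit_boundary_small Upper unit length of microsatellites (bp).
#' @param unit_boundary_mini Upper unit length of minisatellites (bp).
#' @param satellite_min_units Copy-number boundary between large tandem
#'   repeats and satellite DNAs.
#' @return Character vector of class labels (one of `simple_polyA`,
#'   `simple_polyC`, `microsatellite`, `minisatellite`,
#'   `large_tandem_repeat`, `satellite`, `rejected`).
#' @examples
#' classify_ssr(5, 60)          # microsatellite
#' classify_ssr(1, 49, "A")     # rejected
#' classify_ssr(120, 51)        # satellite
#' @export
classify_ssr <- function(unit_length, copy_number, unit = NA_character_,
                         min_units_small = 50, unit_boundary_small = 10,
                         unit_boundary_mini = 60, satellite_min_units = 50) {
  n <- max(length(unit_length), length(copy_number))
  unit_length <- rep_len(unit_length, n)
  copy_number <- rep_len(copy_number, n)
  unit <- rep_len(unit, n)
  out <- character(n)
  for (i in seq_len(n)) {
    u <- unit_length[i]; k <- copy_number[i]
    if (u <= unit_boundary_mini) {
      if (k < min_units_small) { out[i] <- "rejected"; next }
      out[i] <-
        if (u == 1) {
          b <- toupper(unit[i])
          if (!is.na(b) && b %in% c("C", "G")) "simple_polyC"
          else "simple_polyA"
        } else if (u <= unit_boundary_small) "microsatellite"
        else "minisatellite"
    } else {
      if (k < 2) { out[i] <- "rejected"; next }
      out[i] <- if (k > satellite_min_units) "satellite"
                else "large_tandem_repeat"
    }
  }
  out
}

#' Classify all arrays of a TRF table
#'
#' Adds an `ssr_class` column (see [classify_ssr()]).
#'
#' @param arrays Data.frame from [parse_trf_dat()] or
#'   [find_exact_tandems()].
#' @param ... Passed to [classify_ssr()].
#' @return The input with an `ssr_class` column.
#' @export
classify_arrays <- function(arrays, ...) {
  arrays$ssr_class <- classify_ssr(arrays$unit_length, arrays$copy_number,
                                   arrays$unit, ...)
  arrays
}

#' Convert classified tandem arrays to GFF3 annotations
#'
#' Retained (non-rejected) arrays become one GFF3 feature each, with the
#' six-attribute schema of the SSR census: `ID`, `ssr_type`, `unit_size`,
#' `unit_seq`, `array_size`, `copy_number`.
#'
#' @param arrays Classified arrays (see [classify_arrays()]).
#' @param seq_lengths Optional named vector of sequence lengths to
#'   register on the result.
#' @return A [GenomicRanges::GRanges] of retained arrays.
#' @export
ssr_to_gff <- function(arrays, seq_lengths = NULL) {
  if (is.null(arrays$ssr_class)) stop("arrays must be classified first")
  keep <- arrays[arrays$ssr_class != "rejected", , drop = FALSE]
  if (nrow(keep)) {
    gr <- GenomicRanges::GRanges(
      keep$seqid, IRanges::IRanges(keep$start, keep$end), strand = "*"
    )
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = "repeatscape", type = "tandem_repeat",
      ID = sprintf("SSR%06d", seq_len(nrow(keep))),
      ssr_type = keep$ssr_class,
      unit_size = keep$unit_length,
      unit_seq = keep$unit,
      array_size = keep$end - keep$start + 1L,
      copy_number = keep$copy_number
    )
  } else {
    gr <- GenomicRanges::GRanges()
  }
  if (!is.null(seq_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seq_lengths)
    GenomeInfoDb::seqlengths(gr) <- seq_lengths
  }
  gr
}

# Is `u` a primitive unit (not itself a tandem of a shorter unit)?
is_primitive_unit <- function(u) {
  n <- nchar(u)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        u == strrep(substr(u, 1L, d), n / d)) return(FALSE)
  }
  TRUE
}

#' Exhaustively find perfect tandem arrays
#'
#' Brute-force detector of every maximal perfect (mismatch-free) tandem
#' run, reported leftmost-anchored with its smallest primitive unit.
#' Serves as an independent oracle for planted perfect arrays; it is not a
#' replacement for a full tandem-repeat detector on real, imperfect
#' arrays.
#'
#' @param sequence Character scalar over `A,C,G,T,N` (N never matches).
#' @param max_unit Largest repeat-unit size to consider (bp).
#' @param min_copies Minimum (possibly fractional) copies to report.
#' @param seqid Sequence name for the output table.
#' @return A data.frame in the [parse_trf_dat()] layout.
#' @examples
#' find_exact_tandems("ACACACAC", max_unit = 2)  # unit "AC" x 4
#' @export
find_exact_tandems <- function(sequence, max_unit = 10, min_copies = 2,
                               seqid = "seq") {
  s <- chars(toupper(sequence))
  n <- length(s)
  isn <- s == "N"
  rows <- list()
  seqstr <- paste(s, collapse = "")
  for (u in seq_len(min(max_unit, max(0L, n - 1L)))) {
    m <- s[seq_len(n - u)] == s[seq_len(n - u) + u] &
      !isn[seq_len(n - u)] & !isn[seq_len(n - u) + u]
    r <- rle(m)
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1L
    j <- which(r$values & r$lengths + u >= u * max(min_copies, 2))
    if (!length(j)) next
    st <- run_starts[j]
    arr_len <- r$lengths[j] + u
    unit <- substring(seqstr, st, st + u - 1L)
    prim <- vapply(unit, is_primitive_unit, logical(1), USE.NAMES = FALSE)
    if (!any(prim)) next
    st <- st[prim]; arr_len <- arr_len[prim]; unit <- unit[prim]
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = seqid, start = st, end = st + arr_len - 1L,
      unit_length = u, copy_number = arr_len / u, consensus_size = u,
      percent_matches = 100, percent_indels = 0, score = 2 * arr_len,
      unit = unit,
      sequence = substring(seqstr, st, st + arr_len - 1L)
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seqid = character(), start = integer(), end = integer(),
                      unit_length = integer(), copy_number = numeric(),
                      consensus_size = integer(), percent_matches = numeric(),
                      percent_indels = numeric(), score = numeric(),
                      unit = character(), sequence = character())
  }
  rownames(out) <- NULL
  out
}

#' Count distinct repeat units at 100 % identity
#'
#' Exact de-duplication of repeat-unit sequences, as used for the
#' "number of different repeated units" column of the SSR census.
#'
#' @param units Character vector of repeat-unit sequences.
#' @return Number of distinct units (exact string identity).
#' @export
distinct_units <- function(units) length(unique(toupper(units)))
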