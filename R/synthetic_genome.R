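#' Specify a TE model for planting
#'
#' A TE model is a repeat "species": a main consensus sequence plus the
#' population of (diverged, possibly truncated, possibly nested) genomic
#' copies derived from it. The simulator plants `copy_count` copies, each
#' with a substitution divergence drawn uniformly from `divergence_range`,
#' optional one-sided truncation, and optional single-level nesting inside
#' another planted copy.
#'
#' @param name Model label.
#' @param te_type One of `LINE`, `LTR`, `TIR`, `undetermined`.
#' @param consensus Consensus nucleotide sequence (50--10000 bp, A/C/G/T).
#' @param copy_count Number of copies to plant (>= 0).
#' @param divergence_range Pair of substitution fractions in \[0, 0.5\],
#'   lower <= upper.
#' @param truncation_prob Probability that a copy is truncated at one end
#'   (removing 10--50 % of its length).
#' @param nesting_prob Probability that a copy is inserted inside another
#'   planted TE copy (splitting the host into two truth features that
#'   share a copy identifier).
#' @return A `repeat_model_spec` list.
#' @export
repeat_model <- function(name, consensus, te_type = "undetermined",
                         copy_count = 0, divergence_range = c(0, 0),
                         truncation_prob = 0, nesting_prob = 0) {
  consensus <- toupper(as.character(consensus))
  stopifnot(
    te_type %in% c("LINE", "LTR", "TIR", "undetermined"),
    nchar(consensus) >= 50, nchar(consensus) <= 10000,
    grepl("^[ACGT]+$", consensus),
    copy_count >= 0,
    length(divergence_range) == 2,
    divergence_range[1] >= 0, divergence_range[2] <= 0.5,
    divergence_range[1] <= divergence_range[2],
    truncation_prob >= 0, truncation_prob <= 1,
    nesting_prob >= 0, nesting_prob <= 1
  )
  structure(list(name = name, te_type = te_type, consensus = consensus,
                 copy_count = as.integer(copy_count),
                 divergence_range = divergence_range,
                 truncation_prob = truncation_prob,
                 nesting_prob = nesting_prob),
            class = "repeat_model_spec")
}

#' Specify SSR arrays for planting
#'
#' @param ssr_class One of `simple_polyA`, `simple_polyC`,
#'   `microsatellite`, `minisatellite`, `large_tandem_repeat`,
#'   `satellite`. Unit lengths must respect the class ranges (1 bp for
#'   simple repeats, 2--10 microsatellite, 11--60 minisatellite, > 60 for
#'   the tandem-array classes).
#' @param unit_length Repeat-unit length (bp).
#' @param copy_number Units per array (> 1, may be fractional).
#' @param count Number of arrays to plant.
#' @return An `ssr_plant_spec` list.
#' @export
ssr_plant <- function(ssr_class, unit_length, copy_number, count = 1) {
  ranges <- list(simple_polyA = c(1, 1), simple_polyC = c(1, 1),
                 microsatellite = c(2, 10), minisatellite = c(11, 60),
                 large_tandem_repeat = c(61, 2000), satellite = c(61, 2000))
  stopifnot(ssr_class %in% names(ranges), copy_number > 1, count >= 1)
  rg <- ranges[[ssr_class]]
  if (unit_length < rg[1] || unit_length > rg[2]) {
    stop("unit_length ", unit_length, " outside the ", ssr_class,
         " range [", rg[1], ", ", rg[2], "]")
  }
  structure(list(ssr_class = ssr_class, unit_length = as.integer(unit_length),
                 copy_number = copy_number, count = as.integer(count)),
            class = "ssr_plant_spec")
}

#' Mutate a consensus into a diverged genomic copy
#'
#' Applies i.i.d. nucleotide substitutions at rate `divergence` (each
#' substitution changes the base) after removing `truncate_5p` /
#' `truncate_3p` bases from the ends. Indels are not modelled.
#'
#' @param consensus Consensus sequence (character).
#' @param divergence Substitution fraction in \[0, 1\].
#' @param truncate_5p,truncate_3p Bases to remove from each end
#'   (their sum must be smaller than the consensus length).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The mutated copy (character), of length
#'   `nchar(consensus) - truncate_5p - truncate_3p`.
#' @export
mutate_copy <- function(consensus, divergence, truncate_5p = 0,
                        truncate_3p = 0, seed = NULL) {
  if (divergence < 0 || divergence > 1) {
    stop("divergence must be in [0, 1]")
  }
  len <- nchar(consensus)
  if (truncate_5p + truncate_3p >= len) {
    stop("truncations leave no sequence")
  }
  if (!is.null(seed)) set.seed(seed)
  s <- chars(substr(consensus, truncate_5p + 1L, len - truncate_3p))
  hit <- runif(length(s)) < divergence
  if (any(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    s[hit] <- vapply(s[hit], function(b) {
      alt[[b]][sample.int(3, 1)]
    }, character(1), USE.NAMES = FALSE)
  }
  paste(s, collapse = "")
}

make_ssr_array_seq <- function(spec) {
  unit <- switch(spec$ssr_class,
    simple_polyA = sample(c("A", "T"), 1),
    simple_polyC = sample(c("C", "G"), 1),
    {
      repeat {
        u <- random_dna(spec$unit_length)
        if (is_primitive_unit(u) && length(unique(chars(u))) > 1) break
      }
      u
    })
  full <- floor(spec$copy_number)
  part <- round((spec$copy_number - full) * nchar(unit))
  list(unit = unit,
       seq = paste0(strrep(unit, full), substr(unit, 1, part)))
}

#' Generate a multi-chromosome synthetic genome with planted repeats
#'
#' Builds i.i.d.-uniform background chromosomes and plants TE copies
#' (diverged, truncated, optionally nested), SSR arrays, N-stretches and
#' coordinate-only context features (genes with exons, CpG-like and
#' S/MAR-like elements), returning the genome together with exact ground
#' truth. Planting is non-overlapping except single-level nesting: a
#' guest TE copy inserted inside a host splits the host into two truth
#' features sharing a `copy_id` (the long-join situation). N-stretches
#' are placed only in background, never inside planted repeats.
#'
#' @param chrom_sizes Named (or auto-named `chr1`...) vector of
#'   chromosome sizes (bp).
#' @param te_specs List of [repeat_model()] specs.
#' @param ssr_specs List of [ssr_plant()] specs.
#' @param n_stretch List with `count`, `min_len`, `max_len` (per genome).
#' @param gene_density Gene-like context features per Mbp.
#' @param context_density CpG-like and S/MAR-like features per Mbp (each).
#' @param seed Integer seed; the run is fully reproducible.
#' @return A `genome_truth` list: `sequences` ([Biostrings::DNAStringSet]),
#'   `truth` (`GRanges` of planted repeats with `class`, `model`,
#'   `te_type`, `ssr_class`, `divergence`, `identity`, `truncated`,
#'   `copy_id`, `unit`, `copy_number`, `sequence` columns), `context`
#'   (`GRanges` of genes/exons/CpG/S-MAR), `n_runs` (`GRanges`), `seed`.
#' @export
generate_genome <- function(chrom_sizes, te_specs = list(),
                            ssr_specs = list(),
                            n_stretch = list(count = 0, min_len = 100,
                                             max_len = 1000),
                            gene_density = 0, context_density = 0,
                            seed = 1) {
  set.seed(seed)
  if (is.null(names(chrom_sizes))) {
    names(chrom_sizes) <- paste0("chr", seq_along(chrom_sizes))
  }
  chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))

  # --- build plant items -------------------------------------------------
  items <- list()
  for (spec in te_specs) {
    for (k in seq_len(spec$copy_count)) {
      div <- runif(1, spec$divergence_range[1], spec$divergence_range[2])
      t5 <- t3 <- 0L
      truncated <- runif(1) < spec$truncation_prob
      if (truncated) {
        amt <- as.integer(nchar(spec$consensus) * runif(1, 0.1, 0.5))
        if (sample(c(TRUE, FALSE), 1)) t5 <- amt else t3 <- amt
      }
      seqv <- mutate_copy(spec$consensus, div, t5, t3)
      region <- substr(spec$consensus, t5 + 1L,
                       nchar(spec$consensus) - t3)
      ident <- mean(chars(seqv) == chars(region))
      items[[length(items) + 1L]] <- list(
        class = "te", model = spec$name, te_type = spec$te_type,
        seq = seqv, divergence = div, identity = ident,
        truncated = truncated,
        nest = runif(1) < spec$nesting_prob,
        unit = NA_character_, copy_number = NA_real_,
        ssr_class = NA_character_
      )
    }
  }
  for (spec in ssr_specs) {
    for (k in seq_len(spec$count)) {
      arr <- make_ssr_array_seq(spec)
      items[[length(items) + 1L]] <- list(
        class = "ssr", model = NA_character_, te_type = NA_character_,
        seq = arr$seq, divergence = 0, identity = 1, truncated = FALSE,
        nest = FALSE, unit = arr$unit, copy_number = spec$copy_number,
        ssr_class = spec$ssr_class
      )
    }
  }

  # --- single-level nesting: attach guests to hosts ----------------------
  te_idx <- which(vapply(items, function(x) x$class == "te", logical(1)))
  guest_idx <- te_idx[vapply(items[te_idx], function(x) x$nest, logical(1))]
  host_pool <- setdiff(te_idx, guest_idx)
  host_pool <- host_pool[vapply(items[host_pool],
                                function(x) nchar(x$seq) >= 100, logical(1))]
  guests_of <- vector("list", length(items))
  unplaced_guests <- c()
  for (g in guest_idx) {
    free <- host_pool[vapply(guests_of[host_pool], is.null, logical(1))]
    if (!length(free)) { unplaced_guests <- c(unplaced_guests, g); next }
    guests_of[[sample(rep(free, 2), 1)]] <- g   # rep() guards length-1 sample
  }
  top_idx <- c(setdiff(seq_along(items), guest_idx), unplaced_guests)

  item_len <- function(i) {
    nchar(items[[i]]$seq) +
      if (!is.null(guests_of[[i]])) nchar(items[[guests_of[[i]]]]$seq) else 0L
  }

  # --- assign items to chromosomes (capacity-checked) --------------------
  free <- as.numeric(chrom_sizes)
  assign_chr <- character(length(items))
  for (i in sample(top_idx)) {
    len <- item_len(i)
    fits <- which(free > len)
    if (!length(fits)) {
      stop("infeasible packing: no chromosome can hold a ", len,
           "-bp plant (fullest: ",
           names(chrom_sizes)[which.max(free)], ")")
    }
    ch <- fits[sample.int(length(fits), 1, prob = free[fits])]
    assign_chr[i] <- names(chrom_sizes)[ch]
    free[ch] <- free[ch] - len
  }

  # --- assemble each chromosome ------------------------------------------
  seqs <- character(length(chrom_sizes))
  names(seqs) <- names(chrom_sizes)
  truth_rows <- list()
  gap_rows <- list()   # background gaps available for N-stretches
  copy_counter <- 0L
  for (ch in names(chrom_sizes)) {
    ids <- top_idx[assign_chr[top_idx] == ch]
    ids <- ids[sample.int(length(ids))]
    planted <- sum(vapply(ids, item_len, integer(1)))
    bg_total <- chrom_sizes[[ch]] - planted
    gaps <- random_composition(bg_total, length(ids) + 1L)
    pos <- 1L
    parts <- character(0)
    for (j in seq_along(ids)) {
      g <- gaps[j]
      if (g > 0) {
        parts <- c(parts, random_dna(g))
        gap_rows[[length(gap_rows) + 1L]] <-
          data.frame(seqid = ch, start = pos, end = pos + g - 1L)
        pos <- pos + g
      }
      i <- ids[j]
      it <- items[[i]]
      gi <- guests_of[[i]]
      if (is.null(gi)) {
        copy_counter <- copy_counter + 1L
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          seqid = ch, start = pos, end = pos + nchar(it$seq) - 1L,
          class = it$class, model = it$model, te_type = it$te_type,
          ssr_class = it$ssr_class, divergence = it$divergence,
          identity = it$identity, truncated = it$truncated,
          copy_id = sprintf("plant_%05d", copy_counter),
          unit = it$unit, copy_number = it$copy_number,
          sequence = it$seq
        )
        parts <- c(parts, it$seq)
        pos <- pos + nchar(it$seq)
      } else {
        # host split by a nested guest
        gu <- items[[gi]]
        hl <- nchar(it$seq)
        cut <- sample(seq(25L, hl - 25L), 1)   # internal split point
        left <- substr(it$seq, 1L, cut)
        right <- substr(it$seq, cut + 1L, hl)
        copy_counter <- copy_counter + 1L
        host_id <- sprintf("plant_%05d", copy_counter)
        copy_counter <- copy_counter + 1L
        guest_id <- sprintf("plant_%05d", copy_counter)
        s1 <- pos; e1 <- pos + nchar(left) - 1L
        s2 <- e1 + 1L; e2 <- e1 + nchar(gu$seq)
        s3 <- e2 + 1L; e3 <- e2 + nchar(right)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          seqid = ch, start = s1, end = e1, class = "te",
          model = it$model, te_type = it$te_type,
          ssr_class = NA_character_, divergence = it$divergence,
          identity = it$identity, truncated = it$truncated,
          copy_id = host_id, unit = NA_character_,
          copy_number = NA_real_, sequence = left)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          seqid = ch, start = s2, end = e2, class = "te",
          model = gu$model, te_type = gu$te_type,
          ssr_class = NA_character_, divergence = gu$divergence,
          identity = gu$identity, truncated = gu$truncated,
          copy_id = guest_id, unit = NA_character_,
          copy_number = NA_real_, sequence = gu$seq)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          seqid = ch, start = s3, end = e3, class = "te",
          model = it$model, te_type = it$te_type,
          ssr_class = NA_character_, divergence = it$divergence,
          identity = it$identity, truncated = it$truncated,
          copy_id = host_id, unit = NA_character_,
          copy_number = NA_real_, sequence = right)
        parts <- c(parts, left, gu$seq, right)
        pos <- e3 + 1L
      }
    }
    g <- gaps[length(gaps)]
    if (g > 0) {
      parts <- c(parts, random_dna(g))
      gap_rows[[length(gap_rows) + 1L]] <-
        data.frame(seqid = ch, start = pos, end = pos + g - 1L)
    }
    seqs[[ch]] <- paste(parts, collapse = "")
    stopifnot(nchar(seqs[[ch]]) == chrom_sizes[[ch]])
  }

  # --- N-stretches in background gaps ------------------------------------
  n_rows <- list()
  gapdf <- do.call(rbind, gap_rows)
  if (n_stretch$count > 0 && !is.null(gapdf)) {
    for (k in seq_len(n_stretch$count)) {
      len <- sample(seq(n_stretch$min_len, n_stretch$max_len), 1)
      ok <- which((gapdf$end - gapdf$start + 1L) >= len)
      if (!length(ok)) next
      gi <- ok[sample.int(length(ok), 1)]
      s <- gapdf$start[gi] +
        sample.int(gapdf$end[gi] - gapdf$start[gi] - len + 2L, 1) - 1L
      e <- s + len - 1L
      ch <- gapdf$seqid[gi]
      substr(seqs[[ch]], s, e) <- strrep("N", len)
      n_rows[[length(n_rows) + 1L]] <- data.frame(seqid = ch, start = s,
                                                  end = e)
      # shrink the gap record so stretches never overlap
      old_end <- gapdf$end[gi]
      gapdf$end[gi] <- s - 1L
      if (e < old_end) {
        gapdf <- rbind(gapdf, data.frame(seqid = ch, start = e + 1L,
                                         end = old_end))
      }
      gapdf <- gapdf[(gapdf$end - gapdf$start + 1L) > 0, , drop = FALSE]
    }
  }

  # --- coordinate-only context features ----------------------------------
  ctx_rows <- list()
  plant_context <- function(type, per_mbp, min_len, max_len) {
    for (ch in names(chrom_sizes)) {
      n <- stats::rpois(1, per_mbp * chrom_sizes[[ch]] / 1e6)
      for (k in seq_len(n)) {
        len <- sample(seq(min_len, max_len), 1)
        if (len >= chrom_sizes[[ch]]) next
        s <- sample.int(chrom_sizes[[ch]] - len, 1)
        ctx_rows[[length(ctx_rows) + 1L]] <<- data.frame(
          seqid = ch, start = s, end = s + len - 1L, type = type,
          ID = sprintf("%s_%s_%03d", type, ch, k), parent = NA_character_)
        if (type == "gene") {   # 2-4 exons inside the gene span
          nex <- sample(2:4, 1)
          bounds <- sort(sample(seq(s, s + len - 1L), 2L * nex))
          for (x in seq_len(nex)) {
            ctx_rows[[length(ctx_rows) + 1L]] <<- data.frame(
              seqid = ch, start = bounds[2L * x - 1L], end = bounds[2L * x],
              type = "exon",
              ID = sprintf("exon_%s_%03d_%d", ch, k, x),
              parent = sprintf("%s_%s_%03d", type, ch, k))
          }
        }
      }
    }
  }
  if (gene_density > 0) plant_context("gene", gene_density, 1000, 10000)
  if (context_density > 0) {
    plant_context("CpG_island", context_density, 200, 1500)
    plant_context("SMAR", context_density, 200, 800)
  }

  to_gr <- function(rows, extra_cols) {
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      gr <- GenomicRanges::GRanges()
    } else {
      gr <- GenomicRanges::GRanges(df$seqid,
                                   IRanges::IRanges(df$start, df$end))
      S4Vectors::mcols(gr) <-
        S4Vectors::DataFrame(df[, extra_cols, drop = FALSE])
    }
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
    sort(gr)
  }

  structure(list(
    sequences = Biostrings::DNAStringSet(seqs),
    truth = to_gr(truth_rows, c("class", "model", "te_type", "ssr_class",
                                "divergence", "identity", "truncated",
                                "copy_id", "unit", "copy_number",
                                "sequence")),
    context = to_gr(ctx_rows, c("type", "ID", "parent")),
    n_runs = to_gr(n_rows, character(0)),
    chrom_sizes = chrom_sizes,
    seed = seed
  ), class = "genome_truth")
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf(paste0("genome_truth: %d chromosome(s), %s bp, %d planted",
                     " repeat feature(s), %d N-run(s), seed %d\n"),
              length(x$sequences),
              format(sum(as.numeric(x$chrom_sizes)), big.mark = ","),
              length(x$truth), length(x$n_runs), x$seed))
  invisible(x)
}

#' Write a synthetic genome and its ground truth to disk
#'
#' FASTA (60-column wrapping, seed recorded in headers), GFF3 truth and
#' context tracks, and a BED of N-runs.
#'
#' @param genome A `genome_truth` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  seqs <- genome$sequences
  names(seqs) <- paste0(names(seqs), " seed=", genome$seed)
  Biostrings::writeXStringSet(seqs, fa, width = 60)
  truth <- file.path(dir, "truth.gff3")
  tg <- genome$truth
  S4Vectors::mcols(tg)$sequence <- NULL   # sequences live in the FASTA
  write_gff3_annotations(tg, truth)
  ctx <- file.path(dir, "context.gff3")
  write_gff3_annotations(genome$context, ctx)
  nbed <- file.path(dir, "n_runs.bed")
  idx <- lapply(names(genome$chrom_sizes), function(ch) {
    r <- genome$n_runs[GenomeInfoDb::seqnames(genome$n_runs) == ch]
    n_index(IRanges::IRanges(GenomicRanges::start(r),
                             GenomicRanges::end(r)),
            genome$chrom_sizes[[ch]])
  })
  names(idx) <- names(genome$chrom_sizes)
  write_n_index_bed(idx, nbed)
  invisible(c(fasta = fa, truth = truth, context = ctx, n_runs = nbed))
}
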