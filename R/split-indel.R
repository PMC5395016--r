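# Split-read detection of large reference indels from long reads: local
# alignment hits, pairing of split hits into events, and corroboration by
# independent reads (the automated stand-in for manual candidate curation).

#' Fraction of a sequence covered by simple tandem repeats
#'
#' Lightweight tandem detector used to skip repeat-dominated long reads
#' (the full-scale pipeline masks reads with a repeat library; at desk scale
#' simple tandems are the confounder that matters for split alignments).
#'
#' @param seq A single sequence.
#' @param max_period Largest tandem period checked.
#' @param min_run Minimum length of a self-matching run (including the first
#'   period) to call a tandem.
#' @return Fraction of positions covered by detected tandem runs.
#' @export
tandem_fraction <- function(seq, max_period = 8L, min_run = 20L) {
  n <- nchar(seq)
  if (n < min_run) return(0)
  x <- utf8ToInt(seq)
  mask <- rep(FALSE, n)
  for (p in seq_len(max_period)) {
    if (n <= p) break
    eq <- x[(p + 1L):n] == x[1L:(n - p)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= (min_run - p))
    for (i in sel) mask[starts[i]:(ends[i] + p)] <- TRUE
  }
  mean(mask)
}

#' Local alignment of long reads against the assembly
#'
#' Seeded local alignment reporting all hits above the length/identity
#' thresholds, with an ambiguity flag when another hit covers at least half
#' of the same read interval within the score margin. Reads whose sequence is
#' more than `mask_threshold` simple-tandem are skipped entirely. For
#' minus-strand hits the read interval refers to the reverse-complemented
#' read, so downstream gap arithmetic is strand-uniform.
#'
#' @param reads A `long_reads` data frame (id, seq) or character vector.
#' @param assembly Reference sequences.
#' @param k Seed k-mer length.
#' @param min_len Minimum hit length (bp).
#' @param min_identity Minimum hit identity.
#' @param margin Score margin for the ambiguity flag.
#' @param mask_threshold Skip reads with a higher tandem fraction; NULL
#'   disables masking.
#' @return Data frame of local hits: read (id), strand, read_start/read_end,
#'   chrom, ref_start/ref_end (all 1-based closed), score, nm, ambiguous,
#'   read_len.
#' @export
local_align <- function(reads, assembly, k = 15, min_len = 40,
                        min_identity = 0.8, margin = 6,
                        mask_threshold = 0.5) {
  if (is.character(reads)) reads <- data.frame(
    id = sprintf("read%05d", seq_along(reads)), seq = reads)
  seqs <- as_chrom_character(assembly)
  use <- rep(TRUE, nrow(reads))
  if (!is.null(mask_threshold)) {
    use <- vapply(reads$seq, tandem_fraction, numeric(1),
                  USE.NAMES = FALSE) <= mask_threshold
  }
  sub <- reads[use, , drop = FALSE]
  h <- cpp_local_hits(seqs, sub$seq, as.integer(k), as.integer(min_len),
                      min_identity, as.integer(margin))
  h$read_len <- nchar(sub$seq)[h$read]
  h$read <- sub$id[h$read]
  h$chrom <- names(seqs)[h$chrom]
  h$ambiguous <- h$ambiguous == 1L
  h
}

#' Detect large indel events from split local hits
#'
#' Selects reads whose alignment splits into two unambiguous local hits on
#' the same chromosome and strand, ordered consistently on read and
#' reference, within `max_distance` on the reference, and together covering
#' more than `min_coverage` of the read. Event size is the read gap between
#' the hits minus the reference gap: positive means bases are missing from
#' the assembly (insertion; they must be inserted), negative means the
#' assembly carries extra bases (deletion); the absolute size is reported.
#'
#' The coverage denominator is the read length as provided (post-trim) by
#' default; pass `raw_lengths` and set `coverage_basis = "raw"` to use
#' original read lengths.
#'
#' @param hits Data frame from [local_align()].
#' @param max_distance Maximum reference distance between the hits (1 Mb).
#' @param min_coverage Minimum combined read coverage of the two hits (0.9,
#'   exclusive).
#' @param min_size Minimum absolute event size emitted (default 50 bp;
#'   smaller gaps belong to the small-indel caller).
#' @param coverage_basis `"trimmed"` (default) or `"raw"`.
#' @param raw_lengths Named numeric vector of original read lengths (by read
#'   id), required for `coverage_basis = "raw"`.
#' @return Data frame of `SplitReadEvent`s: read, chrom, strand, event_type,
#'   size, breakpoint (last reference base of the left hit), ref_distance,
#'   read_gap, ref_gap, coverage.
#' @export
detect_events <- function(hits, max_distance = 1e6, min_coverage = 0.9,
                          min_size = 50, coverage_basis = c("trimmed", "raw"),
                          raw_lengths = NULL) {
  coverage_basis <- match.arg(coverage_basis)
  empty <- data.frame(read = character(0), chrom = character(0),
                      strand = character(0), event_type = character(0),
                      size = numeric(0), breakpoint = integer(0),
                      ref_distance = numeric(0), read_gap = numeric(0),
                      ref_gap = numeric(0), coverage = numeric(0))
  h <- hits[!hits$ambiguous, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  out <- list()
  for (rid in unique(h$read)) {
    hr <- h[h$read == rid, , drop = FALSE]
    hr <- hr[order(hr$read_start), , drop = FALSE]
    if (nrow(hr) < 2L) next
    for (i in seq_len(nrow(hr) - 1L)) {
      h1 <- hr[i, ]; h2 <- hr[i + 1L, ]
      if (h1$chrom != h2$chrom || h1$strand != h2$strand) next
      # consistent ordering on read and reference
      if (h2$read_start <= h1$read_start || h2$ref_start <= h1$ref_start) next
      read_gap <- h2$read_start - h1$read_end - 1L
      ref_gap <- h2$ref_start - h1$ref_end - 1L
      if (ref_gap > max_distance) next
      denom <- if (coverage_basis == "raw") {
        stopifnot(!is.null(raw_lengths))
        unname(raw_lengths[rid])
      } else h1$read_len
      cover <- ((h1$read_end - h1$read_start + 1L) +
                  (h2$read_end - h2$read_start + 1L)) / denom
      if (cover <= min_coverage) next
      size <- read_gap - ref_gap
      if (abs(size) < min_size) next
      out[[length(out) + 1L]] <- data.frame(
        read = rid, chrom = h1$chrom, strand = h1$strand,
        event_type = if (size > 0) "insertion" else "deletion",
        size = abs(size), breakpoint = h1$ref_end,
        ref_distance = ref_gap, read_gap = read_gap, ref_gap = ref_gap,
        coverage = cover)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Corroborate split-read events
#'
#' Clusters events by chromosome, type and breakpoint proximity and keeps
#' clusters supported by at least `min_support` independent reads -- the
#' automated stand-in for the source study's manual inspection of split-read
#' candidates. When a short-read pileup is supplied, a deletion-type
#' singleton (assembly carries extra bases) is also kept if short-read
#' coverage collapses over the extra segment (mean depth below
#' `drop_frac` of the flanking depth).
#'
#' @param events Data frame from [detect_events()].
#' @param min_support Minimum supporting reads per cluster (default 2).
#' @param window Breakpoint clustering window (default 10 bp).
#' @param short_read_pileup Optional `pileup` for the coverage-drop signal.
#' @param drop_frac Coverage-drop threshold (default 0.2).
#' @return Data frame of consolidated events: chrom, event_type, breakpoint
#'   (median), size (median), support, reads.
#' @export
corroborate_events <- function(events, min_support = 2, window = 10,
                               short_read_pileup = NULL, drop_frac = 0.2) {
  empty <- data.frame(chrom = character(0), event_type = character(0),
                      breakpoint = integer(0), size = numeric(0),
                      support = integer(0), reads = character(0))
  if (nrow(events) == 0L) return(empty)
  ev <- events[order(events$chrom, events$event_type, events$breakpoint), ,
               drop = FALSE]
  newgrp <- c(TRUE, ev$chrom[-1] != ev$chrom[-nrow(ev)] |
                ev$event_type[-1] != ev$event_type[-nrow(ev)] |
                diff(ev$breakpoint) > window)
  grp <- cumsum(newgrp)
  out <- lapply(split(ev, grp), function(g) {
    support <- length(unique(g$read))
    keep <- support >= min_support
    bp <- as.integer(round(median(g$breakpoint)))
    size <- median(g$size)
    if (!keep && !is.null(short_read_pileup) &&
        g$event_type[1] == "deletion") {
      dep <- pileup_depth(short_read_pileup)[[g$chrom[1]]]
      if (!is.null(dep)) {
        inside <- dep[pmin(bp + seq_len(max(1, round(size))), length(dep))]
        flank <- dep[pmax(1, bp - 50):bp]
        keep <- mean(inside) < drop_frac * max(mean(flank), 1)
      }
    }
    if (!keep) return(NULL)
    data.frame(chrom = g$chrom[1], event_type = g$event_type[1],
               breakpoint = bp, size = size, support = support,
               reads = paste(unique(g$read), collapse = ","))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
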