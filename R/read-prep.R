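# Short-read preprocessing: quality trimming, adapter clipping, length
# filtering and paired-end bookkeeping, with Table-1-style stage statistics.

#' Quality-trim reads from both ends
#'
#' Low-quality bases (< threshold) are trimmed from both the 5' and 3' end of
#' each read until two or more consecutive bases with quality >= threshold
#' are observed; reads with no such anchor at either end are discarded
#' (emptied). The kept span is a contiguous substring and may retain internal
#' low-quality bases.
#'
#' @param reads A `short_reads` data frame (id, seq, qual, mate).
#' @param threshold Phred threshold (default 20).
#' @return The reads data frame with trimmed `seq`/`qual`; discarded reads
#'   have zero-length sequences.
#' @export
trim_quality <- function(reads, threshold = 20) {
  if (nrow(reads) == 0L) return(reads)
  b <- cpp_trim_bounds(reads$qual, as.integer(threshold))
  keep <- b[, 1] > 0L
  reads$seq <- ifelse(keep, substr(reads$seq, b[, 1], b[, 2]), "")
  reads$qual <- ifelse(keep, substr(reads$qual, b[, 1], b[, 2]), "")
  reads
}

#' Clip 3'-anchored adapter sequence
#'
#' Truncates each read before the leftmost occurrence of an adapter prefix.
#' An occurrence must either contain the full adapter or run to the read end,
#' overlap by at least `min_match` bases, and have at most
#' `floor(overlap * max_mismatch)` mismatches (fastx_clipper-like semantics;
#' the source protocol does not state these parameters, so they are exposed,
#' documented defaults).
#'
#' @param reads A `short_reads` data frame.
#' @param adapters Character vector of adapter sequences (uppercase).
#' @param min_match Minimum adapter overlap (default 5).
#' @param max_mismatch Maximum mismatch fraction within the overlap
#'   (default 0.10).
#' @return The reads data frame with clipped `seq`/`qual`.
#' @export
clip_adapter <- function(reads, adapters, min_match = 5, max_mismatch = 0.10) {
  stopifnot(length(adapters) > 0)
  if (nrow(reads) == 0L) return(reads)
  keep_len <- cpp_clip_length(reads$seq, toupper(adapters),
                              as.integer(min_match), max_mismatch)
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

#' Length-filter reads
#'
#' Reads shorter than `min_len` (default 32 bp) are discarded.
#'
#' @param reads A `short_reads` data frame.
#' @param min_len Minimum length to keep.
#' @return Logical vector: keep (TRUE) / discard (FALSE) per read.
#' @export
filter_length <- function(reads, min_len = 32) {
  nchar(reads$seq) >= min_len
}

#' Paired-end bookkeeping
#'
#' Combines the survival status of the two mates of each pair: if both
#' survive the pair stays paired; if exactly one was discarded the survivor
#' is relabelled "unpaired" (treated as single-end downstream); if both were
#' discarded nothing is emitted.
#'
#' @param mate1_kept,mate2_kept Logical vectors (one element per pair).
#' @return Character vector per pair: `"paired"`, `"unpaired1"` (mate1
#'   survives alone), `"unpaired2"`, or `"dropped"`.
#' @export
pair_bookkeeping <- function(mate1_kept, mate2_kept) {
  stopifnot(length(mate1_kept) == length(mate2_kept))
  ifelse(mate1_kept & mate2_kept, "paired",
         ifelse(mate1_kept, "unpaired1",
                ifelse(mate2_kept, "unpaired2", "dropped")))
}

#' Preprocess short reads
#'
#' Full preprocessing in the stated order: quality trimming, adapter
#' clipping, length filter (< `min_len` discarded), then pair bookkeeping
#' for paired libraries. Stage statistics mirror a sequencing-run processing
#' table: reads remaining after each step and the count of unpaired
#' survivors.
#'
#' @param reads A `short_reads` data frame.
#' @param adapters Adapter sequences to clip.
#' @param q_threshold Phred trimming threshold (default 20).
#' @param min_len Minimum surviving read length (default 32).
#' @return List with `reads` (surviving reads, mates of broken pairs
#'   relabelled `"unpaired"`) and `stats` (a `prep_stats` list: input_reads,
#'   after_quality_trim, after_adapter_trim, after_pairing, unpaired_count).
#' @export
preprocess_reads <- function(reads, adapters = character(0), q_threshold = 20,
                             min_len = 32) {
  input <- nrow(reads)
  r <- trim_quality(reads, q_threshold)
  ok_trim <- nchar(r$seq) > 0L
  after_trim <- sum(ok_trim)
  if (length(adapters)) r <- clip_adapter(r, adapters)
  keep <- filter_length(r, min_len)
  after_clip <- sum(keep)

  paired <- r$mate %in% c("mate1", "mate2")
  if (any(paired)) {
    pairs <- sort(unique(r$pair[paired]))
    i1 <- match(pairs, ifelse(r$mate == "mate1", r$pair, NA_integer_))
    i2 <- match(pairs, ifelse(r$mate == "mate2", r$pair, NA_integer_))
    status <- pair_bookkeeping(keep[i1], keep[i2])
    stat_of_pair <- status[match(r$pair, pairs)]
    relabel <- (r$mate == "mate1" & stat_of_pair == "unpaired1") |
      (r$mate == "mate2" & stat_of_pair == "unpaired2")
    r$mate[relabel] <- "unpaired"
    after_pairing <- sum(keep & stat_of_pair == "paired", na.rm = TRUE)
    unpaired_count <- sum(keep & relabel, na.rm = TRUE)
  } else {
    after_pairing <- NA_integer_
    unpaired_count <- 0L
  }
  out <- r[keep, , drop = FALSE]
  stats <- list(input_reads = input, after_quality_trim = after_trim,
                after_adapter_trim = after_clip,
                after_pairing = after_pairing,
                unpaired_count = unpaired_count)
  class(stats) <- "prep_stats"
  list(reads = out, stats = stats)
}

#' @export
print.prep_stats <- function(x, ...) {
  cat("read preprocessing:\n")
  cat(sprintf("  input reads:          %10d\n", x$input_reads))
  cat(sprintf("  after quality trim:   %10d\n", x$after_quality_trim))
  cat(sprintf("  after adapter trim:   %10d\n", x$after_adapter_trim))
  if (!is.na(x$after_pairing))
    cat(sprintf("  after pairing:        %10d (%d unpaired)\n",
                x$after_pairing, x$unpaired_count))
  invisible(x)
}
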