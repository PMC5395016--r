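# Alignment and pileup: a desk-scale seed-and-extend unique mapper (the role
# an external short-read aligner plays at full scale), alignment filtering,
# gapped pileup construction and depth-of-coverage profiles.

#' Map reads to an assembly
#'
#' Seed-and-extend mapping with gapped (affine) extension. A read is placed
#' `unique` only if its best placement beats every other candidate by at
#' least `margin` score points; ties within the margin give `multiple`
#' (mapping confidence 0), matching the downstream rule that only uniquely
#' mapped reads are piled up. Both strands are searched. Mapping confidence
#' is 60 for unique placements and 0 otherwise; only the >= 20 cutoff
#' semantics matter downstream.
#'
#' @param reads A `short_reads` data frame, or any data frame with `seq`
#'   (and optionally id/mate/pair columns).
#' @param assembly Reference sequences (DNAStringSet or named character).
#' @param k Seed k-mer length.
#' @param margin Minimum score separation for a unique call.
#' @param score_slack Maximum score deficit from a perfect match
#'   (match +1, mismatch -2, gap open -3, gap extend -1) before a read is
#'   considered unmapped.
#' @return Alignment records: one row per read with chrom, pos (1-based),
#'   strand, mapq, cigar, nm, score, placement, mate/pair bookkeeping and
#'   `seq_ref` (read sequence oriented to the reference).
#' @export
map_reads <- function(reads, assembly, k = 21, margin = 6, score_slack = 16) {
  seqs <- as_chrom_character(assembly)
  m <- cpp_map_reads(seqs, reads$seq, as.integer(k), as.integer(margin),
                     as.integer(score_slack))
  m$chrom <- names(seqs)[m$chrom]
  m$id <- if (!is.null(reads$id)) reads$id else
    sprintf("read%07d", seq_len(nrow(reads)))
  m$mate <- if (!is.null(reads$mate)) reads$mate else "single"
  m$pair <- if (!is.null(reads$pair)) reads$pair else NA_integer_
  m$seq_ref <- ifelse(m$strand == "-", revcomp(reads$seq), reads$seq)
  m
}

#' Filter alignment records
#'
#' Removes multiple/unmapped placements and records below the mapping
#' confidence cutoff (default >= 20), then flags proper pairs: mates uniquely
#' mapped on the same chromosome, inward-oriented, with a span inside
#' `insert_bounds`. When `insert_bounds` is NULL the bounds are estimated as
#' mean +/- 4 sd of the spans of the first 10,000 surviving pairs. Improper
#' pairs are flagged, not removed (each mate still contributes to pileups if
#' uniquely mapped).
#'
#' @param records Records from [map_reads()].
#' @param min_confidence MAPQ-like cutoff (default 20).
#' @param insert_bounds Length-2 numeric (lo, hi) or NULL.
#' @return Filtered records with a `proper_pair` column (NA for single-end).
#' @export
filter_alignments <- function(records, min_confidence = 20,
                              insert_bounds = NULL) {
  r <- records[records$placement == "unique" &
                 records$mapq >= min_confidence, , drop = FALSE]
  r$proper_pair <- NA
  paired <- r$mate %in% c("mate1", "mate2")
  if (any(paired)) {
    i1 <- which(r$mate == "mate1")
    i2 <- which(r$mate == "mate2")
    j <- match(r$pair[i1], r$pair[i2])
    have <- !is.na(j)
    a <- i1[have]; b <- i2[j[have]]
    same <- r$chrom[a] == r$chrom[b] & r$strand[a] != r$strand[b]
    ref_len <- function(cig) {
      ops <- gregexpr("[0-9]+[MIDNSHP=X]", cig)
      vapply(regmatches(cig, ops), function(x) {
        op <- substring(x, nchar(x))
        n <- as.integer(substring(x, 1, nchar(x) - 1L))
        sum(n[op %in% c("M", "D", "N", "=", "X")])
      }, integer(1))
    }
    enda <- r$pos[a] + ref_len(r$cigar[a]) - 1L
    endb <- r$pos[b] + ref_len(r$cigar[b]) - 1L
    span <- pmax(enda, endb) - pmin(r$pos[a], r$pos[b]) + 1L
    fwd_first <- ifelse(r$strand[a] == "+", r$pos[a] <= r$pos[b],
                        r$pos[b] <= r$pos[a])
    inward <- same & fwd_first
    if (is.null(insert_bounds)) {
      est <- span[inward][seq_len(min(10000L, sum(inward, na.rm = TRUE)))]
      est <- est[!is.na(est)]
      if (length(est) >= 2) {
        insert_bounds <- c(max(0, mean(est) - 4 * sd(est)),
                           mean(est) + 4 * sd(est))
      } else insert_bounds <- c(0, Inf)
    }
    proper <- inward & span >= insert_bounds[1] & span <= insert_bounds[2]
    proper[is.na(proper)] <- FALSE
    r$proper_pair[a] <- proper
    r$proper_pair[b] <- proper
    r$proper_pair[paired & is.na(r$proper_pair)] <- FALSE
  }
  attr(r, "insert_bounds") <- insert_bounds
  r
}

#' Build a gapped pileup
#'
#' Tallies per-position base counts (A/C/G/T/N) from the retained alignment
#' records and collects anchored indel alleles: insertions and deletions are
#' left-normalised and anchored at the base immediately left of the event.
#' Every aligned base contributes to exactly one column; deletion-spanned
#' reference positions receive no base count (the deletion is counted at its
#' anchor only).
#'
#' @param records Filtered records from [filter_alignments()] (must carry
#'   `seq_ref`).
#' @param assembly Reference sequences.
#' @return A `pileup` object: list with `counts` (per-chromosome 5 x L
#'   integer matrices, rows A/C/G/T/N), `indels` (chrom, anchor, type
#'   ins/del, len, seq, count), `ref` (chromosome sequences).
#' @export
build_pileup <- function(records, assembly) {
  seqs <- as_chrom_character(assembly)
  r <- records[!is.na(records$chrom), , drop = FALSE]
  ci <- match(r$chrom, names(seqs))
  p <- cpp_build_pileup(seqs, ci, r$pos, r$cigar, r$seq_ref)
  names(p$counts) <- names(seqs)
  p$indels$chrom <- names(seqs)[p$indels$chrom]
  p$ref <- seqs
  class(p) <- "pileup"
  p
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup over", length(x$counts), "chromosome(s),",
      sum(vapply(x$counts, ncol, integer(1))), "positions,",
      nrow(x$indels), "indel alleles\n")
  invisible(x)
}

#' Per-position depth of a pileup
#' @param pileup A `pileup` object.
#' @return Named list of integer depth vectors, one per chromosome.
#' @export
pileup_depth <- function(pileup) {
  lapply(pileup$counts, colSums)
}

#' Merge pileups (pooled dataset)
#'
#' Column-wise sum of base counts and indel allele counts; the pooled
#' dataset is the union of both individuals' retained alignments.
#'
#' @param p1,p2 `pileup` objects over the same assembly.
#' @return A pooled `pileup`.
#' @export
merge_pileups <- function(p1, p2) {
  stopifnot(identical(names(p1$counts), names(p2$counts)))
  out <- p1
  for (cn in names(p1$counts)) out$counts[[cn]] <- p1$counts[[cn]] + p2$counts[[cn]]
  all <- rbind(p1$indels, p2$indels)
  if (nrow(all) > 0L) {
    agg <- stats::aggregate(count ~ chrom + anchor + type + len + seq,
                            data = all, FUN = sum)
    out$indels <- agg[order(agg$chrom, agg$anchor), , drop = FALSE]
    rownames(out$indels) <- NULL
  } else {
    out$indels <- all
  }
  out
}

#' Depth-of-coverage profile
#'
#' Fraction of assembly positions with depth >= t, per threshold, per
#' chromosome and in total, plus the count of effective sites (depth >= 10 by
#' default thresholds) used as the denominator of error/allele rates.
#'
#' @param pileup A `pileup` object.
#' @param thresholds Depth thresholds (default 1, 5, 10).
#' @return Data frame: chrom, length, then `cov_ge_<t>` (count) and
#'   `frac_ge_<t>` per threshold, with a "total" row.
#' @export
coverage_profile <- function(pileup, thresholds = c(1, 5, 10)) {
  dep <- pileup_depth(pileup)
  rows <- lapply(names(dep), function(cn) {
    d <- dep[[cn]]
    counts <- vapply(thresholds, function(t) sum(d >= t), numeric(1))
    out <- data.frame(chrom = cn, length = length(d))
    for (i in seq_along(thresholds)) {
      out[[paste0("cov_ge_", thresholds[i])]] <- counts[i]
      out[[paste0("frac_ge_", thresholds[i])]] <- counts[i] / length(d)
    }
    out
  })
  df <- do.call(rbind, rows)
  tot <- df[1, , drop = FALSE]
  tot$chrom <- "total"
  tot$length <- sum(df$length)
  for (t in thresholds) {
    tot[[paste0("cov_ge_", t)]] <- sum(df[[paste0("cov_ge_", t)]])
    tot[[paste0("frac_ge_", t)]] <- tot[[paste0("cov_ge_", t)]] / tot$length
  }
  rbind(df, tot)
}
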