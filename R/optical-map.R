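# Optical-map concordance: in-silico restriction digestion, dynamic-
# programming alignment of fragment patterns under a sizing-error model,
# discordance classification (classes 1-5) and gap-size estimation.

#' Construct a restriction map
#'
#' @param fragments Ordered fragment lengths (bp), all positive.
#' @param map_id Identifier (typically the chromosome / molecule name).
#' @param source `"in_silico"` or `"optical"`.
#' @param cut_sites For in-silico maps, the 1-based position of the last base
#'   of each fragment except the final one (cut coordinates).
#' @return A `restriction_map` object.
#' @export
restriction_map <- function(fragments, map_id = "map", source = "in_silico",
                            cut_sites = NULL) {
  fragments <- as.numeric(fragments)
  stopifnot(all(fragments > 0))
  structure(list(map_id = map_id, fragments = fragments, source = source,
                 cut_sites = cut_sites), class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat("restriction_map", x$map_id, "(", x$source, "):", length(x$fragments),
      "fragments,", sum(x$fragments), "bp\n")
  invisible(x)
}

#' In-silico restriction digestion
#'
#' Cuts a sequence after `cut_offset` bases of each non-overlapping
#' occurrence of the recognition sequence (defaults: SwaI, ATTTAAAT, blunt
#' cut after base 4). Runs of N never match. Fragment lengths always sum to
#' the sequence length.
#'
#' @param sequence A single sequence (character or DNAString) over
#'   A/C/G/T/N.
#' @param recognition Recognition sequence.
#' @param cut_offset Cut position within the site.
#' @param map_id Map identifier.
#' @return A `restriction_map` (source `"in_silico"`); empty sequence gives
#'   an empty map.
#' @export
digest_in_silico <- function(sequence, recognition = "ATTTAAAT",
                             cut_offset = 4L, map_id = "map") {
  s <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(as.character(sequence))
  L <- length(s)
  if (L == 0L)
    return(restriction_map(numeric(0), map_id = map_id,
                           cut_sites = integer(0)))
  hits <- Biostrings::start(Biostrings::matchPattern(recognition, s,
                                                     fixed = TRUE))
  # greedy non-overlapping occurrences
  keep <- integer(0)
  last <- -nchar(recognition)
  for (h in hits) {
    if (h - last >= nchar(recognition)) { keep <- c(keep, h); last <- h }
  }
  cuts <- keep + cut_offset - 1L          # last base of the left fragment
  cuts <- cuts[cuts >= 1L & cuts < L]
  frags <- diff(c(0L, cuts, L))
  restriction_map(frags, map_id = map_id, cut_sites = cuts)
}

# Block score under the sizing model: matched runs agree within a normal
# sizing error of sd = cv * max(size_insilico, sd_floor_len); merging
# fragments into a run is penalised per extra fragment.
block_score <- function(sum_i, sum_o, a, b, params) {
  sdv <- params$cv * max(sum_i, params$sd_floor_len)
  z <- (sum_o - sum_i) / sdv
  params$match_bonus - z^2 / 2 - params$merge_penalty * (a + b - 2)
}

skip_i_penalty <- function(size, params) {
  if (size < params$small_cutoff) params$skip_small
  else params$skip_insilico_large
}

skip_o_penalty <- function(size, params) {
  if (size < params$small_cutoff) params$skip_small
  else params$skip_optical
}

# merge_penalty defaults to 4 ~ -ln(0.02), the log-likelihood cost of one
# missed/extra cut at the stated 2% cut-error rate.
map_align_params <- function(cv = 0.05, max_merge = 3, match_bonus = 3,
                             merge_penalty = 4, skip_optical = 2,
                             skip_small = 1, skip_insilico_large = 3,
                             small_cutoff = 1200, sd_floor_len = 2000) {
  list(cv = cv, max_merge = max_merge, match_bonus = match_bonus,
       merge_penalty = merge_penalty, skip_optical = skip_optical,
       skip_small = skip_small,
       skip_insilico_large = skip_insilico_large,
       small_cutoff = small_cutoff, sd_floor_len = sd_floor_len)
}

#' Align an in-silico map against an optical map
#'
#' Global dynamic-programming alignment of two ordered fragment-length maps.
#' Blocks pair a run of 1..`max_merge` in-silico fragments with a run of
#' 1..`max_merge` optical fragments and are scored by size agreement under a
#' normal sizing-error model (sd = cv x size); missed/extra fragments can be
#' skipped at a penalty (fragments below the detection-limit cutoff skip
#' cheaply on either side, emulating desorption). Ties are broken
#' deterministically:
#' higher score, then fewer merged fragments, then the leftmost structure.
#'
#' @param insilico,optical `restriction_map` objects.
#' @param cv Sizing coefficient of variation.
#' @param max_merge Maximum fragments per block on each side.
#' @param ... Scoring overrides passed to the parameter constructor
#'   (match_bonus, merge_penalty, skip_optical, skip_small,
#'   skip_insilico_large, small_cutoff, sd_floor_len).
#' @return A `map_alignment`: `blocks` (i_start, i_end, j_start, j_end,
#'   size_i, size_o, diff), `unmatched` (side "insilico"/"optical", start,
#'   end, size), total `score`, and in-silico fragment coordinates when the
#'   input map carries cut sites.
#' @export
align_maps <- function(insilico, optical, cv = 0.05, max_merge = 3, ...) {
  stopifnot(inherits(insilico, "restriction_map"),
            inherits(optical, "restriction_map"))
  fi <- insilico$fragments; fo <- optical$fragments
  stopifnot(length(fi) > 0, length(fo) > 0)
  params <- map_align_params(cv = cv, max_merge = max_merge, ...)
  n <- length(fi); m <- length(fo)
  csi <- cumsum(c(0, fi)); cso <- cumsum(c(0, fo))

  NEGS <- -1e18
  score <- matrix(NEGS, n + 1, m + 1)
  merges <- matrix(0L, n + 1, m + 1)
  from_i <- matrix(NA_integer_, n + 1, m + 1)
  from_j <- matrix(NA_integer_, n + 1, m + 1)
  move <- matrix(NA_character_, n + 1, m + 1)
  score[1, 1] <- 0
  better <- function(s1, m1, s2, m2) {
    s1 > s2 + 1e-12 || (abs(s1 - s2) <= 1e-12 && m1 < m2)
  }
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    bs <- NEGS; bm <- 0L; bi <- NA_integer_; bj <- NA_integer_; bmv <- NA_character_
    for (a in 1:min(params$max_merge, i)) for (b in 1:min(params$max_merge, j)) {
      if (i - a < 0 || j - b < 0) next
      prev <- score[i - a + 1, j - b + 1]
      if (prev <= NEGS / 2) next
      s <- prev + block_score(csi[i + 1] - csi[i - a + 1],
                              cso[j + 1] - cso[j - b + 1], a, b, params)
      mm <- merges[i - a + 1, j - b + 1] + (a + b - 2L)
      if (better(s, mm, bs, bm)) {
        bs <- s; bm <- mm; bi <- i - a; bj <- j - b; bmv <- "match"
      }
    }
    if (i >= 1 && score[i, j + 1] > NEGS / 2) {
      s <- score[i, j + 1] - skip_i_penalty(fi[i], params)
      mm <- merges[i, j + 1]
      if (better(s, mm, bs, bm)) {
        bs <- s; bm <- mm; bi <- i - 1L; bj <- j; bmv <- "skip_i"
      }
    }
    if (j >= 1 && score[i + 1, j] > NEGS / 2) {
      s <- score[i + 1, j] - skip_o_penalty(fo[j], params)
      mm <- merges[i + 1, j]
      if (better(s, mm, bs, bm)) {
        bs <- s; bm <- mm; bi <- i; bj <- j - 1L; bmv <- "skip_j"
      }
    }
    score[i + 1, j + 1] <- bs; merges[i + 1, j + 1] <- bm
    from_i[i + 1, j + 1] <- bi; from_j[i + 1, j + 1] <- bj
    move[i + 1, j + 1] <- bmv
  }

  # traceback
  blocks <- list(); unmatched <- list()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    mv <- move[i + 1, j + 1]
    pi <- from_i[i + 1, j + 1]; pj <- from_j[i + 1, j + 1]
    if (mv == "match") {
      blocks[[length(blocks) + 1L]] <- data.frame(
        i_start = pi + 1L, i_end = i, j_start = pj + 1L, j_end = j,
        size_i = csi[i + 1] - csi[pi + 1], size_o = cso[j + 1] - cso[pj + 1])
    } else if (mv == "skip_i") {
      unmatched[[length(unmatched) + 1L]] <- data.frame(
        side = "insilico", start = i, end = i, size = fi[i])
    } else {
      unmatched[[length(unmatched) + 1L]] <- data.frame(
        side = "optical", start = j, end = j, size = fo[j])
    }
    i <- pi; j <- pj
  }
  blocks <- if (length(blocks)) do.call(rbind, rev(blocks)) else
    data.frame(i_start = integer(0), i_end = integer(0),
               j_start = integer(0), j_end = integer(0),
               size_i = numeric(0), size_o = numeric(0))
  blocks$diff <- blocks$size_o - blocks$size_i
  um <- if (length(unmatched)) do.call(rbind, rev(unmatched)) else
    data.frame(side = character(0), start = integer(0), end = integer(0),
               size = numeric(0))
  # group adjacent unmatched fragments on the same side into runs
  if (nrow(um) > 1L) {
    grp <- cumsum(c(TRUE, !(um$side[-1] == um$side[-nrow(um)] &
                              um$start[-1] == um$end[-nrow(um)] + 1L)))
    um <- do.call(rbind, lapply(split(um, grp), function(g) {
      data.frame(side = g$side[1], start = min(g$start), end = max(g$end),
                 size = sum(g$size))
    }))
    rownames(um) <- NULL
  }
  structure(list(blocks = blocks, unmatched = um,
                 score = score[n + 1, m + 1],
                 insilico = insilico, optical = optical, params = params),
            class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat("map_alignment:", nrow(x$blocks), "matched blocks,",
      nrow(x$unmatched), "unmatched runs, score", round(x$score, 2), "\n")
  invisible(x)
}

# Assembly coordinate interval of in-silico fragments f1..f2 (needs cut
# sites on the in-silico map).
fragment_coords <- function(insilico, f1, f2) {
  cs <- c(0L, insilico$cut_sites, sum(insilico$fragments))
  c(start = cs[f1] + 1L, end = cs[f2 + 1L])
}

#' Classify map-sequence discordances
#'
#' Groups the discordant elements of a map alignment (unmatched fragment
#' runs, size-discordant blocks, merged blocks implying cut-site
#' disagreements) into regions (within `window` bp on the assembly) and
#' assigns each region one of five classes: 1 = physical gap in the
#' pseudomolecule (region overlaps an annotated gap); 2 = missed or extra
#' fragment of at least `min_event` bp; 3 = significant size difference
#' (>= `min_event`); 4 = multiple different cut sites in the same area;
#' 5 = multiple different cut sites plus multiple unmatched fragments with
#' non-comparable totals (possible misassembly). Sub-threshold class-2/3
#' events are suppressed.
#'
#' @param alignment A `map_alignment` whose in-silico map carries cut sites.
#' @param gaps Optional gap annotation data frame (chrom, start, end).
#' @param chrom Chromosome name of the aligned sequence (for gap matching
#'   and reporting).
#' @param min_event Minimum annotated event size (default 5000 bp).
#' @param window Region grouping window (default 100 kb).
#' @param size_frac Total-size disagreement fraction for class 5
#'   (default 0.10).
#' @return Data frame: class, chrom, start, end, magnitude, n_cut_diff,
#'   n_unmatched, detail.
#' @export
classify_discordances <- function(alignment, gaps = NULL, chrom = NA_character_,
                                  min_event = 5000, window = 1e5,
                                  size_frac = 0.10) {
  ins <- alignment$insilico
  stopifnot(!is.null(ins$cut_sites) || length(ins$fragments) <= 1)
  blocks <- alignment$blocks
  um <- alignment$unmatched
  el <- list()
  # matched blocks: size differences and cut-site disagreements. A block
  # merged on one side only (1:k / k:1) is explained by a single missed or
  # extra cut -- routine measurement noise -- and is not discordant by
  # itself; a block merged on both sides (>= 2:2) means the cut positions
  # disagree between sequence and map, the signature of a different
  # restriction site.
  for (r in seq_len(nrow(blocks))) {
    co <- fragment_coords(ins, blocks$i_start[r], blocks$i_end[r])
    cut_diff <- (blocks$i_end[r] > blocks$i_start[r]) &&
      (blocks$j_end[r] > blocks$j_start[r])
    el[[length(el) + 1L]] <- data.frame(
      kind = "block", start = co[1], end = co[2],
      size_i = blocks$size_i[r], size_o = blocks$size_o[r],
      diff = abs(blocks$diff[r]), cut_diff = cut_diff, unmatched = 0L)
  }
  for (r in seq_len(nrow(um))) {
    if (um$side[r] == "insilico") {
      co <- fragment_coords(ins, um$start[r], um$end[r])
      nun <- um$end[r] - um$start[r] + 1L
      el[[length(el) + 1L]] <- data.frame(
        kind = "unmatched_i", start = co[1], end = co[2], size_i = um$size[r],
        size_o = 0, diff = um$size[r], cut_diff = FALSE, unmatched = nun)
    } else {
      # anchor an unmatched optical run between its flanking in-silico blocks
      left <- blocks[blocks$j_end < um$start[r], , drop = FALSE]
      anchor <- if (nrow(left)) fragment_coords(ins, 1L,
                                                max(left$i_end))[["end"]] else 0L
      nun <- um$end[r] - um$start[r] + 1L
      el[[length(el) + 1L]] <- data.frame(
        kind = "unmatched_o", start = anchor, end = anchor + 1L,
        size_i = 0, size_o = um$size[r], diff = um$size[r], cut_diff = FALSE,
        unmatched = nun)
    }
  }
  el <- do.call(rbind, el)
  # keep only discordant elements
  disc <- el[el$kind != "block" | el$cut_diff | el$diff >= min_event, ,
             drop = FALSE]
  out <- data.frame(class = integer(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    magnitude = numeric(0), n_cut_diff = integer(0),
                    n_unmatched = integer(0), detail = character(0))
  if (nrow(disc) == 0L) return(out)
  disc <- disc[order(disc$start), , drop = FALSE]
  grp <- cumsum(c(TRUE, disc$start[-1] - disc$end[-nrow(disc)] > window))
  for (g in split(disc, grp)) {
    start <- min(g$start); end <- max(g$end)
    n_cut <- sum(g$cut_diff)
    n_un <- sum(g$unmatched)
    tot_i <- sum(g$size_i); tot_o <- sum(g$size_o)
    size_dis <- abs(tot_o - tot_i) / max(tot_i, 1)
    unmatched_bp <- sum(g$diff[g$kind != "block"])
    blockdiff_bp <- if (any(g$kind == "block")) max(g$diff[g$kind == "block"])
                    else 0
    gap_hit <- !is.null(gaps) && nrow(gaps) > 0 &&
      any((is.na(chrom) | gaps$chrom == chrom) &
            gaps$end >= start & gaps$start <= end)
    cls <- if (gap_hit) 1L
      else if (n_cut >= 2L && n_un >= 2L && size_dis > size_frac) 5L
      else if (n_cut >= 2L) 4L
      else if (unmatched_bp >= min_event) 2L
      else if (blockdiff_bp >= min_event) 3L
      else NA_integer_
    if (is.na(cls)) next
    mag <- if (cls == 1L) sum(g$size_o[g$kind == "unmatched_o"])
           else if (cls == 2L) unmatched_bp
           else if (cls == 3L) blockdiff_bp
           else abs(tot_o - tot_i)
    out <- rbind(out, data.frame(
      class = cls, chrom = chrom, start = start, end = end, magnitude = mag,
      n_cut_diff = n_cut, n_unmatched = n_un,
      detail = paste0(g$kind, collapse = ",")))
  }
  rownames(out) <- NULL
  out
}

#' Estimate a physical gap's size from the optical map
#'
#' Sums the optical fragments left unmatched at the gap location. Zero (with
#' a `supported = FALSE` attribute) means the map does not support the gap.
#'
#' @param alignment A `map_alignment` with in-silico cut sites.
#' @param gap_location Data frame / list with start, end (assembly
#'   coordinates of the gap).
#' @param window Search window around the gap (default 100 kb).
#' @return Numeric gap size (bp) with attribute `supported`.
#' @export
estimate_gap_size <- function(alignment, gap_location, window = 1e5) {
  ins <- alignment$insilico
  um <- alignment$unmatched
  um <- um[um$side == "optical", , drop = FALSE]
  total <- 0
  for (r in seq_len(nrow(um))) {
    left <- alignment$blocks[alignment$blocks$j_end < um$start[r], ,
                             drop = FALSE]
    anchor <- if (nrow(left)) fragment_coords(ins, 1L,
                                              max(left$i_end))[["end"]] else 0L
    if (anchor >= gap_location$start - window &&
        anchor <= gap_location$end + window)
      total <- total + um$size[r]
  }
  structure(total, supported = total > 0)
}
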