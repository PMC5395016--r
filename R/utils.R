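# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that a SimConfig seed
# fully determines every artifact (no hidden global randomness).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Stage-specific child seed, kept below .Machine$integer.max.
child_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 9973) %% 2147483587
}

#' Reverse complement of character sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors as plain character vectors.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a genome-like object (DNAStringSet, DNAString, named character) to a
# named character vector of chromosome sequences.
as_chrom_character <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is(x, "DNAString")) {
    out <- stats::setNames(as.character(x), "chr1")
  } else if (is.character(x)) {
    out <- x
  } else if (is.list(x) && !is.null(x$seq)) {
    return(as_chrom_character(x$seq))
  } else {
    stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
         " as a set of chromosome sequences")
  }
  if (is.null(names(out))) names(out) <- paste0("chr", seq_along(out))
  out
}

as_dnastringset <- function(x) {
  x <- as_chrom_character(x)
  Biostrings::DNAStringSet(x)
}

# Phred+33 helpers
qual_to_int <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)
int_to_qual <- function(v) vapply(v, function(x) intToUtf8(x + 33L), character(1))

# Random DNA string(s) with a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Sample m integer positions in [lo, hi] pairwise >= spacing apart, also
# >= spacing away from positions in `avoid`. Errors out if the space is too
# tight after max_tries rejection rounds.
sample_spaced <- function(m, lo, hi, spacing, avoid = integer(0),
                          max_tries = 200L) {
  if (m == 0L) return(integer(0))
  if ((hi - lo + 1) < m * spacing)
    stop("insufficient placeable space: need ", m, " positions with spacing ",
         spacing, " in [", lo, ", ", hi, "]")
  chosen <- integer(0)
  for (t in seq_len(max_tries)) {
    need <- m - length(chosen)
    cand <- sample.int(hi - lo + 1L, min(need * 4L, hi - lo + 1L)) + lo - 1L
    for (p in cand) {
      if (length(chosen) >= m) break
      taken <- c(chosen, avoid)
      if (length(taken) == 0L || all(abs(p - taken) >= spacing))
        chosen <- c(chosen, p)
    }
    if (length(chosen) >= m) return(sort(chosen))
  }
  stop("insufficient placeable space after ", max_tries, " sampling rounds")
}

# Positions covered by ranges (two-column matrix/data.frame start,end) as an
# integer mask lookup; used for non-repeat placement.
in_ranges <- function(pos, ranges) {
  if (is.null(ranges) || nrow(ranges) == 0L) return(rep(FALSE, length(pos)))
  ir <- IRanges::IRanges(ranges$start, ranges$end)
  IRanges::overlapsAny(IRanges::IRanges(pos, pos), ir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
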