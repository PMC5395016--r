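# Independent oracles used by the tests. These deliberately avoid the
# package's own algorithms: plain string comparison, exhaustive enumeration
# and direct recounting.

# Positions at which two equal-length sequences differ.
brute_diff <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

rc_chr <- function(s) {
  chartr("ACGT", "TGCA", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

# Exhaustive ungapped placement of a read on a genome string: returns the
# best (position, strand, mismatches) over every offset on both strands.
brute_map <- function(read, genome) {
  gb <- utf8ToInt(genome)
  best <- list(mism = Inf)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else rc_chr(read)
    rb <- utf8ToInt(s)
    L <- length(rb)
    for (p in seq_len(length(gb) - L + 1L)) {
      m <- sum(gb[p:(p + L - 1L)] != rb)
      if (m < best$mism) best <- list(pos = p, strand = strand, mism = m)
    }
  }
  best
}

# Brute-force replay pileup: per-record CIGAR walk tallying base counts,
# written independently of the C++ engine.
brute_pileup_counts <- function(records, ref) {
  counts <- lapply(ref, function(s)
    matrix(0L, 5, nchar(s), dimnames = list(c("A", "C", "G", "T", "N"), NULL)))
  code <- function(ch) {
    i <- match(ch, c("A", "C", "G", "T"))
    ifelse(is.na(i), 5L, i)
  }
  for (r in seq_len(nrow(records))) {
    if (is.na(records$chrom[r])) next
    cn <- records$chrom[r]
    m <- regmatches(records$cigar[r],
                    gregexpr("[0-9]+[MIDNS]", records$cigar[r]))[[1]]
    ops <- substring(m, nchar(m))
    lens <- as.integer(substring(m, 1, nchar(m) - 1L))
    rp <- records$pos[r]; qp <- 1L
    sq <- strsplit(records$seq_ref[r], "")[[1]]
    for (k in seq_along(ops)) {
      if (ops[k] == "M") {
        for (t in 0:(lens[k] - 1L))
          counts[[cn]][code(sq[qp + t]), rp + t] <-
            counts[[cn]][code(sq[qp + t]), rp + t] + 1L
        rp <- rp + lens[k]; qp <- qp + lens[k]
      } else if (ops[k] == "I") qp <- qp + lens[k]
      else if (ops[k] == "D") rp <- rp + lens[k]
      else if (ops[k] == "S") qp <- qp + lens[k]
      else if (ops[k] == "N") rp <- rp + lens[k]
    }
  }
  counts
}

# Exhaustive enumeration of all fragment-map alignments under the same block
# and skip scoring as align_maps(), with the same tie-break (score, then
# fewer merged fragments). Feasible for maps of <= 8 fragments a side.
brute_align_maps <- function(fi, fo, cv = 0.05, max_merge = 3, ...) {
  params <- refgrade:::map_align_params(cv = cv, max_merge = max_merge, ...)
  best <- list(score = -Inf, merges = Inf, blocks = NULL)
  recurse <- function(i, j, score, merges, blocks) {
    n <- length(fi); m <- length(fo)
    if (i > n && j > m) {
      if (score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 && merges < best$merges)) {
        best <<- list(score = score, merges = merges, blocks = blocks)
      }
      return(invisible())
    }
    if (i <= n && j <= m) {
      for (a in 1:min(max_merge, n - i + 1L)) {
        for (b in 1:min(max_merge, m - j + 1L)) {
          s <- refgrade:::block_score(sum(fi[i:(i + a - 1L)]),
                                      sum(fo[j:(j + b - 1L)]), a, b, params)
          recurse(i + a, j + b, score + s, merges + (a + b - 2L),
                  rbind(blocks, data.frame(i_start = i, i_end = i + a - 1L,
                                           j_start = j, j_end = j + b - 1L)))
        }
      }
    }
    if (i <= n)
      recurse(i + 1L, j, score - refgrade:::skip_i_penalty(fi[i], params),
              merges, blocks)
    if (j <= m)
      recurse(i, j + 1L, score - refgrade:::skip_o_penalty(fo[j], params),
              merges, blocks)
  }
  recurse(1L, 1L, 0, 0L, NULL)
  best
}
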