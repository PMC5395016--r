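# Mapping, alignment filtering, pileup construction and coverage profiles.

toy_genome <- function(seed = 51, n = 10000) {
  set.seed(seed)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

test_that("the mapper places error-free reads uniquely, flags exact-repeat
          reads multiple, and agrees with exhaustive alignment", {
  g <- toy_genome()
  # plant an exact two-copy repeat
  unit <- substr(g[[1]], 2001, 2400)
  g[[1]] <- paste0(substr(g[[1]], 1, 6000), unit, substr(g[[1]], 6401, 10000))

  r_uniq <- substr(g[[1]], 501, 560)
  r_rep <- substr(g[[1]], 2101, 2160)        # inside both repeat copies
  set.seed(52)
  r_mm <- substr(g[[1]], 4001, 4060)
  substr(r_mm, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                  substr(r_mm, 30, 30))[1]
  reads <- data.frame(id = c("u", "rep", "mm"), seq = c(r_uniq, r_rep, r_mm))
  m <- map_reads(reads, g)
  expect_equal(m$placement, c("unique", "multiple", "unique"))
  expect_equal(m$pos[1], 501)
  expect_equal(m$mapq[c(1, 3)], c(60, 60))
  expect_equal(m$mapq[2], 0)
  # one-mismatch read: same placement as the exhaustive oracle, one mismatch
  oracle <- brute_map(r_mm, g[[1]])
  expect_equal(m$pos[3], oracle$pos)
  expect_equal(m$nm[3], 1)
  expect_equal(oracle$mism, 1)
  # reverse-complement reads are found on the minus strand
  mrc <- map_reads(data.frame(id = "rc", seq = rc_chr(r_uniq)), g)
  expect_equal(mrc$strand, "-")
  expect_equal(mrc$pos, 501)
})

test_that("alignment filtering enforces the confidence cutoff and flags
          proper pairs by span", {
  rec <- data.frame(
    id = c("a", "a", "b", "c", "c"),
    chrom = "chr1", pos = c(100L, 300L, 500L, 1000L, 11000L),
    strand = c("+", "-", "+", "+", "-"),
    mapq = c(60L, 60L, 19L, 60L, 60L),
    cigar = "50M", nm = 0L, score = 50L,
    placement = c("unique", "unique", "unique", "unique", "unique"),
    mate = c("mate1", "mate2", "single", "mate1", "mate2"),
    pair = c(1L, 1L, NA, 2L, 2L),
    seq_ref = strrep("A", 50))
  out <- filter_alignments(rec, min_confidence = 20,
                           insert_bounds = c(100, 1000))
  # confidence 19 removed (>= 20 boundary)
  expect_false("b" %in% out$id)
  # inward pair with span 250 within bounds: proper
  expect_true(all(out$proper_pair[out$id == "a"]))
  # mates 10 kb apart with a 1 kb bound: kept individually, not proper
  expect_true(all(out$id %in% c("a", "c")))
  expect_false(any(out$proper_pair[out$id == "c"]))
  # single-end records keep proper_pair NA
  rec2 <- rec[rec$id == "b", ]; rec2$mapq <- 60L
  out2 <- filter_alignments(rec2, insert_bounds = c(100, 1000))
  expect_true(is.na(out2$proper_pair))
})

test_that("pileups count every aligned base once and anchor indels at the
          base to the left", {
  g <- toy_genome(seed = 53, n = 3000)
  # one clean 36 bp read: 36 columns of depth 1
  rd <- substr(g[[1]], 1001, 1036)
  m <- map_reads(data.frame(id = "x", seq = rd), g)
  p <- build_pileup(m, g)
  d <- pileup_depth(p)[[1]]
  expect_equal(sum(d), 36)
  expect_true(all(d[1001:1036] == 1))
  expect_equal(nrow(p$indels), 0)

  # two overlapping reads disagreeing at one site: two base_counts entries
  rd2 <- substr(g[[1]], 1010, 1045)
  mid <- 1020 - 1010 + 1
  substr(rd2, mid, mid) <- setdiff(c("A", "C", "G", "T"),
                                   substr(rd2, mid, mid))[1]
  m2 <- map_reads(data.frame(id = c("x", "y"), seq = c(rd, rd2)), g)
  p2 <- build_pileup(m2, g)
  col <- p2$counts[[1]][, 1020]
  expect_equal(sum(col), 2)
  expect_equal(sum(col > 0), 2)

  # a read with a 2 bp deletion: one anchored (del, 2) allele; the spanned
  # reference positions get no base counts from it
  rd3 <- paste0(substr(g[[1]], 2001, 2040), substr(g[[1]], 2043, 2078))
  m3 <- map_reads(data.frame(id = "z", seq = rd3), g)
  expect_match(m3$cigar, "D")
  p3 <- build_pileup(m3, g)
  expect_equal(nrow(p3$indels), 1)
  expect_equal(p3$indels$type, "del")
  expect_equal(p3$indels$len, 2L)
  # left-normalised anchor: recompute by the shift rule from the raw site
  # (first deleted base d shifts left while s[d-1] == s[d+len-1])
  d <- 2041L; s <- g[[1]]
  while (d > 1L &&
         substr(s, d - 1L, d - 1L) == substr(s, d + 1L, d + 1L)) d <- d - 1L
  expect_equal(p3$indels$anchor, d - 1L)

  # depth conservation: total depth equals total aligned M bases
  aligned <- sum(vapply(m3$cigar, function(cg) {
    mm <- regmatches(cg, gregexpr("[0-9]+M", cg))[[1]]
    sum(as.integer(sub("M", "", mm)))
  }, numeric(1)))
  expect_equal(sum(pileup_depth(p3)[[1]]), aligned)
})

test_that("the C++ pileup engine matches a brute-force per-read replay", {
  cfg <- small_config(seed = 57, genome_length = 3e4, n_chromosomes = 1,
                      depth = 4, n_genes = 2)
  sim <- simulate_study(cfg)
  prep <- preprocess_reads(sim$reads2, cfg$adapters)
  rec <- filter_alignments(map_reads(prep$reads, sim$assembly))
  rec <- rec[seq_len(min(150, nrow(rec))), ]
  p <- build_pileup(rec, sim$assembly)
  oracle <- brute_pileup_counts(rec, as_chr <- stats::setNames(
    as.character(sim$assembly), names(sim$assembly)))
  expect_equal(unname(p$counts[[1]]), unname(oracle[[1]]))
})

test_that("coverage profiles report fractions per threshold", {
  g <- toy_genome(seed = 59, n = 2000)
  # no reads: all fractions zero
  rec0 <- data.frame(id = character(0), chrom = character(0), pos = integer(0),
                     strand = character(0), mapq = integer(0),
                     cigar = character(0), nm = integer(0), score = integer(0),
                     placement = character(0), mate = character(0),
                     pair = integer(0), seq_ref = character(0))
  p0 <- build_pileup(rec0, g)
  cov0 <- coverage_profile(p0)
  expect_true(all(cov0$frac_ge_1 == 0))
  # one read of length L over genome G: fraction L / G at threshold 1
  rd <- substr(g[[1]], 101, 150)
  p1 <- build_pileup(map_reads(data.frame(id = "a", seq = rd), g), g)
  cov1 <- coverage_profile(p1, thresholds = 1)
  expect_equal(cov1$frac_ge_1[cov1$chrom == "chr1"], 50 / 2000)
})

test_that("SAM round trip: ingested records rebuild the identical pileup", {
  cfg <- small_config(seed = 61, genome_length = 2e4, n_chromosomes = 1,
                      depth = 3, n_genes = 0)
  sim <- simulate_study(cfg)
  prep <- preprocess_reads(sim$reads1, cfg$adapters)
  rec <- filter_alignments(map_reads(prep$reads, sim$assembly))
  f <- tempfile(fileext = ".sam")
  write_sam(rec, sim$assembly, f)
  back <- read_sam(f)
  p1 <- build_pileup(rec, sim$assembly)
  p2 <- build_pileup(back[back$placement == "unique", ], sim$assembly)
  expect_equal(p1$counts, p2$counts)
  expect_equal(p1$indels, p2$indels)
})
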