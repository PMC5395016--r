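# In-silico digestion, fragment-map alignment and discordance
# classification.

test_that("in-silico digestion cuts after base 4 of each SwaI site and
          conserves length", {
  set.seed(81)
  bg <- function(n) paste(sample(c("A", "C", "G"), n, TRUE), collapse = "")

  # no site: a single full-length fragment
  d0 <- digest_in_silico(bg(5000))
  expect_equal(d0$fragments, 5000)

  # site starting at 1-based 3997 (0-based 3996) in 10 kb: fragments
  # [4000, 6000]
  s <- paste0(bg(3996), "ATTTAAAT", bg(10000 - 3996 - 8))
  d1 <- digest_in_silico(s)
  expect_equal(d1$fragments, c(4000, 6000))
  # oracle: splitting the string at the cut reproduces the pieces
  expect_equal(nchar(substr(s, 1, d1$cut_sites[1])), 4000)

  # two sites: three fragments summing to the total length
  s2 <- paste0(bg(1000), "ATTTAAAT", bg(2000), "ATTTAAAT", bg(500))
  d2 <- digest_in_silico(s2)
  expect_equal(length(d2$fragments), 3)
  expect_equal(sum(d2$fragments), nchar(s2))

  # N runs never match the recognition sequence
  sn <- paste0(bg(100), "ATTNAAAT", strrep("N", 50), bg(100))
  expect_equal(length(digest_in_silico(sn)$fragments), 1)

  # empty sequence: empty map
  expect_equal(length(digest_in_silico("")$fragments), 0)

  # conservation property over random sequences (AT-rich to force sites)
  for (i in 1:10) {
    r <- paste(sample(c("A", "T", "A", "T", "C", "G"), 20000, TRUE),
               collapse = "")
    expect_equal(sum(digest_in_silico(r)$fragments), 20000)
  }
})

test_that("map alignment matches identical maps 1:1 and merges fragments
          across missed cuts", {
  mi <- restriction_map(c(50000, 30000, 20000), "m", "in_silico")
  # identical maps: all 1:1 blocks, nothing unmatched
  al <- align_maps(mi, restriction_map(c(50000, 30000, 20000), "m", "optical"))
  expect_equal(nrow(al$blocks), 3)
  expect_true(all(al$blocks$i_end - al$blocks$i_start == 0))
  expect_equal(nrow(al$unmatched), 0)

  # optical [50k, 30k] vs in-silico [50k, 12k, 18k]: blocks 1:1 and 2:1,
  # nothing unmatched -- checked against exhaustive enumeration
  mi2 <- restriction_map(c(50000, 12000, 18000), "m", "in_silico")
  mo2 <- restriction_map(c(50000, 30000), "m", "optical")
  al2 <- align_maps(mi2, mo2)
  expect_equal(nrow(al2$blocks), 2)
  expect_equal(al2$blocks$i_end[2] - al2$blocks$i_start[2], 1)
  expect_equal(nrow(al2$unmatched), 0)
  oracle <- brute_align_maps(mi2$fragments, mo2$fragments)
  expect_equal(al2$score, oracle$score, tolerance = 1e-9)
  expect_equal(al2$blocks[, c("i_start", "i_end", "j_start", "j_end")],
               oracle$blocks, ignore_attr = TRUE)

  # a 6 kb in-silico fragment absent from the optical map: unmatched run
  mi3 <- restriction_map(c(40000, 6000, 35000), "m", "in_silico")
  mo3 <- restriction_map(c(40000, 35000), "m", "optical")
  al3 <- align_maps(mi3, mo3)
  expect_equal(nrow(al3$unmatched), 1)
  expect_equal(al3$unmatched$side, "insilico")
  expect_equal(al3$unmatched$size, 6000)
})

test_that("dynamic programming equals exhaustive enumeration on random maps
          of up to 8 fragments", {
  set.seed(83)
  for (rep in 1:25) {
    ni <- sample(2:8, 1); no <- sample(2:8, 1)
    fi <- round(runif(ni, 2000, 60000))
    fo <- round(runif(no, 2000, 60000))
    # half the time, derive the optical map from the in-silico one so that
    # realistic near-matches occur
    if (rep %% 2 == 0) {
      fo <- round(fi * rnorm(ni, 1, 0.05))
      drop <- sample(ni, 1)
      fo <- fo[-drop]
    }
    al <- align_maps(restriction_map(fi, "a", "in_silico"),
                     restriction_map(fo, "a", "optical"))
    oracle <- brute_align_maps(fi, fo)
    expect_equal(al$score, oracle$score, tolerance = 1e-9)
    expect_equal(al$blocks[, c("i_start", "i_end", "j_start", "j_end")],
                 oracle$blocks, ignore_attr = TRUE)
  }
})

test_that("discordances classify into the five classes with the 5 kb
          suppression threshold", {
  mk_ins <- function(frags) {
    cs <- cumsum(frags)
    restriction_map(frags, "chr1", "in_silico",
                    cut_sites = cs[-length(cs)])
  }
  # class 1: an unmatched region coinciding with an annotated gap
  mi <- mk_ins(c(40000, 6000, 35000))
  mo <- restriction_map(c(40000, 35000), "chr1", "optical")
  al <- align_maps(mi, mo)
  gaps <- data.frame(chrom = "chr1", start = 41000, end = 42000)
  d1 <- classify_discordances(al, gaps = gaps, chrom = "chr1")
  expect_equal(d1$class, 1L)
  # without the gap annotation the same region is class 2 (>= 5 kb)
  d2 <- classify_discordances(al, chrom = "chr1")
  expect_equal(d2$class, 2L)
  expect_equal(d2$magnitude, 6000)

  # an extra 6 kb optical fragment, no gap: class 2
  mi2 <- mk_ins(c(40000, 35000))
  mo2 <- restriction_map(c(40000, 6000, 35000), "chr1", "optical")
  d3 <- classify_discordances(align_maps(mi2, mo2), chrom = "chr1")
  expect_equal(d3$class, 2L)

  # a matched block 6 kb off (40 kb vs 46 kb, still the best explanation
  # under the sizing model): class 3
  mi3 <- mk_ins(c(42000, 40000, 35000))
  mo3 <- restriction_map(c(42000, 46000, 35000), "chr1", "optical")
  d4 <- classify_discordances(align_maps(mi3, mo3), chrom = "chr1")
  expect_equal(d4$class, 3L)
  expect_equal(d4$magnitude, 6000)

  # a 4 kb unmatched fragment: suppressed (below 5 kb)
  mi4 <- mk_ins(c(40000, 4000, 35000))
  mo4 <- restriction_map(c(40000, 35000), "chr1", "optical")
  d5 <- classify_discordances(align_maps(mi4, mo4), chrom = "chr1")
  expect_equal(nrow(d5), 0)

  # genuinely different cut sites (crossed fragment sizes force both-side
  # merges) in one area: class 4. A plain missed cut (1:2 merge) is noise.
  mi6 <- mk_ins(c(30000, 8000, 9000, 30000, 8000, 9000, 30000))
  mo6 <- restriction_map(c(30000, 12000, 5000, 30000, 12000, 5000, 30000),
                         "chr1", "optical")
  al6 <- align_maps(mi6, mo6)
  d6 <- classify_discordances(al6, chrom = "chr1")
  expect_equal(d6$class, 4L)
  # the same missed-cut-only pattern alone raises nothing
  mo7 <- restriction_map(c(30000, 17000, 30000, 17000, 30000), "chr1",
                         "optical")
  expect_equal(nrow(classify_discordances(align_maps(mi6, mo7),
                                          chrom = "chr1")), 0)
})

test_that("gap sizes are the sum of unmatched optical fragments at the gap",
{
  mk_ins <- function(frags) {
    cs <- cumsum(frags)
    restriction_map(frags, "chr1", "in_silico",
                    cut_sites = cs[-length(cs)])
  }
  # two unmatched optical fragments at one location: 3,100 + 4,200 = 7,300
  mi <- mk_ins(c(40000, 50000))
  mo <- restriction_map(c(40000, 3100, 4200, 50000), "chr1", "optical")
  al <- align_maps(mi, mo)
  gs <- estimate_gap_size(al, list(start = 40000, end = 40001))
  expect_equal(as.numeric(gs), 7300)
  expect_true(attr(gs, "supported"))

  # a single 600 bp unmatched fragment (small-gap regime)
  mo2 <- restriction_map(c(40000, 600, 50000), "chr1", "optical")
  gs2 <- estimate_gap_size(align_maps(mi, mo2), list(start = 40000,
                                                     end = 40001))
  expect_equal(as.numeric(gs2), 600)

  # no unmatched fragments: 0, flagged unsupported
  gs3 <- estimate_gap_size(align_maps(mi, restriction_map(
    c(40000, 50000), "chr1", "optical")), list(start = 40000, end = 40001))
  expect_equal(as.numeric(gs3), 0)
  expect_false(attr(gs3, "supported"))
})

test_that("a zero-noise optical map aligns back to the digest with no
          discordances", {
  cfg <- sim_config(seed = 89, genome_length = 4e5, n_chromosomes = 1,
                    n_genes = 0, optical_cv = 0, missing_cut_prob = 0,
                    extra_cut_prob = 0, min_fragment = 0,
                    large_insertion_sizes = numeric(0))
  g <- simulate_genome(cfg)
  om <- simulate_optical_map(g$genome, cfg)
  dig <- digest_in_silico(as.character(g$genome[[1]]), map_id = "chr1")
  al <- align_maps(dig, om[[1]])
  expect_equal(nrow(al$unmatched), 0)
  expect_true(all(al$blocks$i_end - al$blocks$i_start == 0))
  expect_true(all(al$blocks$diff == 0))
  expect_equal(nrow(classify_discordances(al, chrom = "chr1")), 0)
})
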