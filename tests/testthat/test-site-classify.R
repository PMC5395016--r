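# R/N/A/L classification, dataset combination into the five genotype
# classes, small-indel calling and rate arithmetic.

test_that("single-site classification follows the inclusive frequency
          thresholds", {
  # depth 9: low depth
  expect_equal(classify_site(c(A = 7, C = 2), "A"), "L")
  # depth 10, 8 ref / 2 alt: reference (0.80 >= 0.80)
  expect_equal(classify_site(c(A = 8, C = 2), "A"), "R")
  # depth 10, 4 ref / 6 same alt: allelic (both >= 0.40)
  expect_equal(classify_site(c(A = 4, C = 6), "A"), "A")
  # depth 12, 2 ref / 10 same alt: non-reference (0.833 >= 0.80)
  expect_equal(classify_site(c(A = 2, C = 10), "A"), "N")
  # depth 10, 7 ref / 3 alt: none of the rules -> unresolved precursor
  expect_equal(classify_site(c(A = 7, C = 3), "A"), "U")
  # vectorised classifier agrees on the same columns
  sc <- make_site_calls(data.frame(ref_n = c(7, 8, 4, 2, 7),
                                   alt_n = c(2, 2, 6, 10, 3)))
  expect_equal(sc$sites$chr1$cat, c("L", "R", "A", "N", "U"))
})

test_that("dataset combination reproduces the five genotype classes", {
  spec1 <- data.frame(ref_n = c(16, 1, 1, 10, 0, 16),
                      alt_n = c(2, 17, 17, 9, 0, 2))
  spec2 <- data.frame(ref_n = c(17, 2, 18, 19, 0, 3),
                      alt_n = c(1, 16, 1, 1, 0, 16))
  specp <- data.frame(ref_n = spec1$ref_n + spec2$ref_n,
                      alt_n = spec1$alt_n + spec2$alt_n)
  c1 <- make_site_calls(spec1); c2 <- make_site_calls(spec2)
  cp <- make_site_calls(specp)
  comb <- combine_datasets(c1, c2, cp)$combined$chr1
  # (R,R,R) -> reference; (N,N same alt) -> sequencing error;
  # (N,R,A-or-N pooled) -> allele between; (A,R,.) -> allele within ind1;
  # (L,L,L) -> low depth; (R,N) -> allele between (either order)
  expect_equal(comb$class,
               c("reference", "sequencing_error", "allele_between",
                 "allele_within", "low_depth", "allele_between"))
  expect_equal(comb$carrier[4], "ind1")
  expect_equal(comb$alt[2], "C")

  # conflicting non-reference alleles across datasets stay unresolved
  c1b <- make_site_calls(data.frame(ref_n = 1, alt_n = 17, alt = "C"))
  c2b <- make_site_calls(data.frame(ref_n = 1, alt_n = 17, alt = "G"))
  cpb <- make_site_calls(data.frame(ref_n = 2, alt_n = 34, alt = "C"))
  expect_equal(combine_datasets(c1b, c2b, cpb)$combined$chr1$class,
               "unresolved")

  # one individual low depth defers to the pooled category
  c1c <- make_site_calls(data.frame(ref_n = c(1, 4), alt_n = c(4, 1)))
  c2c <- make_site_calls(data.frame(ref_n = c(1, 18), alt_n = c(17, 1)))
  cpc <- make_site_calls(data.frame(ref_n = c(2, 22), alt_n = c(21, 2)))
  combc <- combine_datasets(c1c, c2c, cpc)$combined$chr1
  expect_equal(combc$class, c("sequencing_error", "reference"))
  expect_true(combc$low_confidence[1])
  expect_false(combc$low_confidence[2])

  # pooled depth below an individual depth is rejected
  expect_error(combine_datasets(c1, c2, c1), "pooled depth")
})

test_that("the relaxed within-allele rule needs minimum carrier evidence",
{
  # carrier 13 reads with 4 alternative (0.31, count 4): called, carrier ind2
  c1 <- make_site_calls(data.frame(ref_n = 18, alt_n = 0))
  c2 <- make_site_calls(data.frame(ref_n = 9, alt_n = 4))
  cp <- make_site_calls(data.frame(ref_n = 27, alt_n = 4))
  comb <- combine_datasets(c1, c2, cp)$combined$chr1
  expect_equal(comb$class, "allele_within")
  expect_equal(comb$carrier, "ind2")
  # 3 supporting reads fall below the 4-read floor
  c2b <- make_site_calls(data.frame(ref_n = 10, alt_n = 3))
  cpb <- make_site_calls(data.frame(ref_n = 28, alt_n = 3))
  expect_equal(combine_datasets(c1, c2b, cpb)$combined$chr1$class,
               "unresolved")
})

test_that("small-indel calling emits 1-4 bp errors and allelic indels by the
          same thresholds", {
  # depth 20, 18 supporting a 2 bp deletion: error record (0.90 >= 0.80)
  out <- call_small_indels(make_indel_pileup(20, 18, "del", 2))
  expect_equal(nrow(out$errors), 1)
  expect_equal(out$errors$type, "deletion")
  expect_equal(out$errors$size, 2L)
  expect_equal(nrow(out$allelic), 0)
  # depth 20, 9 insertion / 11 plain: allelic indel (0.45 and 0.55 >= 0.40)
  out <- call_small_indels(make_indel_pileup(20, 9, "ins", 1))
  expect_equal(nrow(out$errors), 0)
  expect_equal(nrow(out$allelic), 1)
  expect_equal(out$allelic$type, "insertion")
  # a 5 bp allele is never emitted
  out <- call_small_indels(make_indel_pileup(20, 19, "ins", 5))
  expect_equal(nrow(out$errors) + nrow(out$allelic), 0)
  # depth below the floor is not assessed
  out <- call_small_indels(make_indel_pileup(9, 9, "del", 1))
  expect_equal(nrow(out$errors) + nrow(out$allelic), 0)
})

test_that("rates per 10,000 nucleotides reproduce the published arithmetic",
{
  expect_equal(compute_rate(4886, 320853150), 0.15)
  expect_equal(compute_rate(6433, 320853150), 0.20)
  expect_equal(compute_rate(250, 320853150), 0.0078)
  expect_equal(compute_rate(0, 1000), 0)
})

test_that("every assessable site gets exactly one combined class and
          lowering the depth floor never loses classified sites", {
  set.seed(67)
  n <- 400
  mk <- function() data.frame(
    ref_n = rpois(n, 12), alt_n = rpois(n, 3),
    alt = sample(c("C", "G", "T"), n, TRUE))
  s1 <- mk(); s2 <- mk()
  sp <- data.frame(ref_n = s1$ref_n + s2$ref_n, alt_n = s1$alt_n + s2$alt_n,
                   alt = s1$alt)
  # pooled counts must dominate: use the same alt base for both individuals
  s2$alt <- s1$alt
  c1 <- make_site_calls(s1); c2 <- make_site_calls(s2)
  cp <- make_site_calls(sp)
  comb <- combine_datasets(c1, c2, cp)$combined$chr1
  classes <- c("reference", "sequencing_error", "allele_within",
               "allele_between", "low_depth", "unresolved")
  expect_true(all(comb$class %in% classes))
  expect_equal(length(comb$class), n)

  # monotonicity: a lower depth floor never decreases non-L classified sites
  n_nonL <- vapply(c(15, 10, 5), function(md) {
    sc <- make_site_calls(s1, min_depth = md)
    sum(sc$sites$chr1$cat != "L")
  }, numeric(1))
  expect_true(all(diff(n_nonL) >= 0))
})
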