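# Effect annotation, assembly correction with liftover, gap placeholders
# and accounting arithmetic.

# A hand-built single-gene genome: 10 bp UTR5, two CDS exons (9 + 6 bp, ATG
# ... TAA with a TGG codon to mutate), 8 bp intron, 10 bp UTR3, flanked by
# intergenic sequence.
toy_gene <- function(strand = "+") {
  utr5 <- "CCCCCCCCCC"
  cds1 <- paste0("ATG", "TGG", "GCT")       # M W A
  intr <- "AAAATTTT"
  cds2 <- paste0("GGA", "TAA")              # G *
  utr3 <- "GGGGGGGGGG"
  body <- paste0(utr5, cds1, intr, cds2, utr3)
  flank5 <- strrep("ACGT", 10)
  flank3 <- strrep("TGCA", 10)
  gene_seq <- if (strand == "+") body else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
  g <- c(chr1 = paste0(flank5, gene_seq, flank3))
  gstart <- nchar(flank5) + 1L
  glen <- nchar(body)
  loc <- function(a, b) {
    if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
    else c(gstart + glen - b, gstart + glen - a)
  }
  iv <- list(gene = loc(1, glen), utr5 = loc(1, 10), cds1 = loc(11, 19),
             intron = loc(20, 27), cds2 = loc(28, 33), utr3 = loc(34, 43))
  genes <- rbind(
    data.frame(chrom = "chr1", type = "gene", start = iv$gene[1],
               end = iv$gene[2], strand = strand, phase = NA, id = "g1",
               parent = NA),
    data.frame(chrom = "chr1", type = "mRNA", start = iv$gene[1],
               end = iv$gene[2], strand = strand, phase = NA, id = "g1.1",
               parent = "g1"),
    data.frame(chrom = "chr1", type = "exon", start = min(iv$utr5[1], iv$cds1[1]),
               end = max(iv$utr5[2], iv$cds1[2]), strand = strand, phase = NA,
               id = "g1.1.e1", parent = "g1.1"),
    data.frame(chrom = "chr1", type = "exon", start = min(iv$cds2[1], iv$utr3[1]),
               end = max(iv$cds2[2], iv$utr3[2]), strand = strand, phase = NA,
               id = "g1.1.e2", parent = "g1.1"),
    data.frame(chrom = "chr1", type = "CDS", start = iv$cds1[1],
               end = iv$cds1[2], strand = strand, phase = 0, id = "g1.1.c1",
               parent = "g1.1"),
    data.frame(chrom = "chr1", type = "CDS", start = iv$cds2[1],
               end = iv$cds2[2], strand = strand, phase = 0, id = "g1.1.c2",
               parent = "g1.1"),
    data.frame(chrom = "chr1", type = "five_prime_UTR", start = iv$utr5[1],
               end = iv$utr5[2], strand = strand, phase = NA, id = "g1.1.u5",
               parent = "g1.1"),
    data.frame(chrom = "chr1", type = "three_prime_UTR", start = iv$utr3[1],
               end = iv$utr3[2], strand = strand, phase = NA, id = "g1.1.u3",
               parent = "g1.1"))
  list(genome = g, genes = genes, iv = iv, gstart = gstart, glen = glen,
       strand = strand)
}

test_that("effect annotation classifies substitutions into the six groups",
{
  tg <- toy_gene("+")
  # TGG -> TAG: nonsense (second codon, middle base)
  pos_w <- tg$iv$cds1[1] + 4L
  # GCT -> GTT: missense; GCT -> GCC: silent (third codon)
  pos_a2 <- tg$iv$cds1[1] + 7L
  pos_a3 <- tg$iv$cds1[1] + 8L
  sites <- data.frame(
    chrom = "chr1",
    pos = c(pos_w, pos_a2, pos_a3, tg$iv$utr5[1] + 2L, tg$iv$intron[1] + 3L,
            2L),
    ref = c("G", "C", "T", "C", "A", "C"),
    alt = c("A", "T", "C", "T", "G", "T"))
  out <- annotate_effect(sites, tg$genes, tg$genome)
  expect_equal(out$effect, c("Nonsense", "Missense", "Silent", "UTR",
                             "Intron", "Intergenic"))
})

test_that("minus-strand sites are evaluated on the coding strand", {
  tg <- toy_gene("-")
  # the TGG codon's middle base G is a C on the genome (minus strand); a
  # genomic C->T substitution reads G->A on the coding strand: TGG->TAG
  pos <- tg$gstart + tg$glen - 1L - (10L + 4L)  # mirror of utr5 + 5th cds base
  expect_equal(substr(tg$genome[[1]], pos, pos), "C")
  out <- annotate_effect(data.frame(chrom = "chr1", pos = pos, ref = "C",
                                    alt = "T"), tg$genes, tg$genome)
  expect_equal(out$effect, "Nonsense")
})

test_that("corrections restore the true genome and the offset map round
          trips", {
  cfg <- small_config(seed = 91, genome_length = 5e4, n_chromosomes = 1,
                      n_genes = 2)
  g <- simulate_genome(cfg)
  inj <- inject_assembly_errors(g, cfg)
  tr <- inj$truth$assembly_errors
  er <- data.frame(chrom = tr$chrom, position = tr$position, type = tr$type,
                   ref_allele = tr$ref_allele,
                   corrected_allele = tr$true_allele, size = tr$size)
  er$type[er$type == "substitution"] <- "snp"
  corr <- apply_corrections(inj$assembly, er)
  # full error set: corrected assembly is byte-identical to the true genome
  expect_identical(as.character(corr$assembly[[1]]),
                   as.character(g$genome[[1]]))

  # substitutions only: length unchanged
  ers <- er[er$type == "snp", ]
  cs <- apply_corrections(inj$assembly, ers)
  expect_equal(Biostrings::width(cs$assembly), Biostrings::width(inj$assembly))

  # a 2 bp insertion error (assembly lacking 2 bp) lengthens by 2; a 2 bp
  # deletion error (assembly carrying 2 extra bp) shortens by 2
  base <- Biostrings::DNAStringSet(c(chrA = strrep("ACGTT", 20)))
  e1 <- data.frame(chrom = "chrA", position = 10, type = "insertion",
                   ref_allele = "-", corrected_allele = "GG", size = 2)
  expect_equal(Biostrings::width(apply_corrections(base, e1)$assembly), 102)
  e2 <- data.frame(chrom = "chrA", position = 10, type = "deletion",
                   ref_allele = "CG", corrected_allele = "-", size = 2)
  expect_equal(Biostrings::width(apply_corrections(base, e2)$assembly), 98)

  # overlapping records are rejected with the offenders listed
  bad <- rbind(e2, data.frame(chrom = "chrA", position = 11,
                              type = "snp", ref_allele = "A",
                              corrected_allele = "C", size = 1))
  expect_error(apply_corrections(base, bad), "overlap")

  # offset-map identity outside corrected intervals, and old->new->old
  om <- corr$offset_map
  probe <- setdiff(seq(100, 4e4, by = 997),
                   unlist(mapply(seq, om$old_start - 1, om$old_end + 1)))
  new <- lift_coordinate(om, rep("chr1", length(probe)), probe)
  back <- lift_coordinate(om, rep("chr1", length(probe)), new,
                          direction = "new_to_old")
  expect_equal(back, probe)
  # positions before any edit are unchanged
  first <- min(om$old_start)
  expect_equal(lift_coordinate(om, "chr1", first - 10L), first - 10L)
})

test_that("gap placeholders insert 1,000 Ns at physical gaps and N runs at
          telomeres", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 500)))
  gaps <- data.frame(chrom = "chr1", pos = c(800L, NA, NA),
                     type = c("physical", "telomere_start", "telomere_end"))
  out <- insert_gap_placeholders(g, gaps)
  s <- as.character(out[[1]])
  expect_equal(nchar(s), 2000 + 3000)
  expect_equal(substr(s, 1, 1000), strrep("N", 1000))
  expect_equal(substr(s, nchar(s) - 999, nchar(s)), strrep("N", 1000))
  # the physical gap sits after original position 800 (now shifted by the
  # telomeric run)
  expect_equal(substr(s, 1801, 2800), strrep("N", 1000))
  # zero gaps: unchanged
  expect_identical(
    as.character(insert_gap_placeholders(g, gaps[0, ])[[1]]),
    as.character(g[[1]]))
})

test_that("assembly accounting reproduces the published totals, genome-size
          range and coverage", {
  acct <- account_assembly(
    sequence_length = 373173519,
    gap_estimates = c(cytological = 9598219, optical = 7290600),
    rdna_bp = 3.7e6)
  expect_equal(unname(acct$total_assembly["cytological"]), 382771738)
  expect_equal(unname(acct$total_assembly["optical"]), 380464119)
  expect_equal(acct$genome_size_range_mbp, c(384.2, 386.5))
  expect_equal(acct$coverage_range_pct, c(96.6, 97.1))
  # zero gaps and no rDNA: total equals the sequence, coverage 100%
  acct0 <- account_assembly(1e6, c(none = 0), rdna_bp = 0)
  expect_equal(unname(acct0$total_assembly), 1e6)
  expect_equal(unname(acct0$coverage_pct), 100)
})

test_that("run summaries recount their inputs and report percentages of
          stage input", {
  # empty inputs: no crash, empty bundle
  expect_equal(length(summarize_run()), 0)

  cfg <- small_config(seed = 93, genome_length = 4e4, n_chromosomes = 1,
                      depth = 15, n_genes = 2)
  sim <- simulate_study(cfg)
  pipe <- run_pipeline(sim)
  rep <- summarize_run(prep_stats = pipe$prep,
                       records = rbind(pipe$records$ind1, pipe$records$ind2),
                       coverage = pipe$coverage, combined = pipe$combined,
                       indel_errors = pipe$indels$errors)
  # error composition equals direct recounts of the call tables
  expect_equal(unname(rep$error_composition["snp"]), nrow(pipe$snp_errors))
  expect_equal(unname(rep$error_composition["total"]),
               nrow(pipe$snp_errors) + nrow(pipe$indels$errors))
  # mapping percentages sum to ~100
  expect_equal(sum(rep$mapping$pct), 100, tolerance = 0.2)
  # preprocessing percentage arithmetic
  expect_equal(rep$preprocessing$pct_quality,
               round(100 * rep$preprocessing$after_quality_trim /
                       rep$preprocessing$input, 1))
  # VCF of the allelic sites is written and parses back
  f <- tempfile(fileext = ".vcf")
  al <- pipe$allelic_snps
  write_vcf(data.frame(chrom = al$chrom, pos = al$pos, ref = al$ref,
                       alt = al$alt, class = al$class), sim$assembly, f)
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, "#")), nrow(al))
})

test_that("read yields and error composition reproduce the published
          arithmetic", {
  expect_equal(read_yield_gbp(c(70387992, 60164564), c(36, 51)), 5.6)
  expect_equal(read_yield_gbp(269062790, 76), 20.4)
  expect_equal(unname(error_composition(3447, 642, 797)["total"]), 4886)
})
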