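# Synthetic-data generator: determinism, composition and ground-truth
# bookkeeping.

test_that("genome simulation is deterministic, hits its GC target and keeps
          non-repeat sequence unique", {
  cfg <- sim_config(seed = 3, genome_length = 1e5, n_chromosomes = 1,
                    gc_fraction = 0.5, repeat_fraction = 0, n_genes = 4,
                    large_insertion_sizes = numeric(0))
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))

  s <- as.character(g1$genome[[1]])
  # no repeats injected: no 50-mer occurs twice
  kmers <- substring(s, 1:(nchar(s) - 49L), 50:nchar(s))
  expect_false(any(duplicated(kmers)))

  # GC within binomial expectation at 1 Mb
  big <- simulate_genome(sim_config(seed = 5, genome_length = 1e6,
                                    n_chromosomes = 1, gc_fraction = 0.5,
                                    n_genes = 0,
                                    large_insertion_sizes = numeric(0)))
  bs <- as.character(big$genome[[1]])
  gc <- sum(strsplit(bs, "")[[1]] %in% c("G", "C")) / nchar(bs)
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
})

test_that("gene models are well-formed: non-overlapping, CDS divisible by 3,
          both strands", {
  cfg <- sim_config(seed = 9, genome_length = 2e5, n_genes = 20)
  g <- simulate_genome(cfg)
  genes <- g$genes[g$genes$type == "gene", ]
  expect_equal(nrow(genes), 20)
  for (cn in unique(genes$chrom)) {
    gg <- genes[genes$chrom == cn, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  expect_setequal(unique(genes$strand), c("+", "-"))
  cds <- g$genes[g$genes$type == "CDS", ]
  cds_len <- tapply(cds$end - cds$start + 1L, cds$parent, sum)
  expect_true(all(cds_len %% 3 == 0))
})

test_that("injected assembly errors are exactly recoverable by sequence
          diff and length bookkeeping", {
  base <- sim_config(seed = 13, genome_length = 6e4, n_chromosomes = 1,
                     n_genes = 2, n_substitutions = 10,
                     n_small_insertions = 0, n_small_deletions = 0,
                     n_between_sites = 0, n_within_sites = 0,
                     large_insertion_sizes = numeric(0),
                     large_deletion_sizes = numeric(0))
  g <- simulate_genome(base)

  # zero errors: assembly identical to the true genome
  cfg0 <- sim_config(seed = 13, genome_length = 6e4, n_chromosomes = 1,
                     n_genes = 2, n_substitutions = 0,
                     n_small_insertions = 0, n_small_deletions = 0,
                     large_insertion_sizes = numeric(0),
                     large_deletion_sizes = numeric(0))
  inj0 <- inject_assembly_errors(g, cfg0)
  expect_identical(as.character(inj0$assembly[[1]]),
                   as.character(g$genome[[1]]))
  expect_equal(nrow(inj0$truth$assembly_errors), 0)

  # 10 substitutions: brute-force diff of the FASTAs recovers the truth
  inj <- inject_assembly_errors(g, base)
  d <- brute_diff(as.character(g$genome[[1]]),
                  as.character(inj$assembly[[1]]))
  expect_setequal(d, inj$truth$assembly_errors$position)
  tr <- inj$truth$assembly_errors
  asm <- as.character(inj$assembly[[1]])
  expect_identical(substring(asm, tr$position, tr$position), tr$ref_allele)

  # one 500 bp large deletion error: assembly retains 500 bp the true genome
  # lacks
  cfg5 <- sim_config(seed = 13, genome_length = 6e4, n_chromosomes = 1,
                     n_genes = 2, n_substitutions = 0,
                     n_small_insertions = 0, n_small_deletions = 0,
                     large_insertion_sizes = numeric(0),
                     large_deletion_sizes = 500)
  inj5 <- inject_assembly_errors(g, cfg5)
  expect_equal(Biostrings::width(inj5$assembly)[1],
               Biostrings::width(g$genome)[1] + 500L)
})

test_that("truth categories are position-disjoint and allelic sites land in
          exactly one individual/haplotype", {
  cfg <- small_config(seed = 17)
  g <- simulate_genome(cfg)
  inj <- inject_assembly_errors(g, cfg)
  ind <- simulate_individuals(g, cfg, truth = inj$truth)

  # disjointness across categories (true-genome frame)
  keys <- c(paste(inj$truth$edits$chrom, inj$truth$edits$pos),
            paste(ind$between$chrom, ind$between$true_pos),
            paste(ind$within$chrom, ind$within$true_pos))
  expect_false(any(duplicated(keys)))

  # between sites: diff of the two individuals' homozygous consensus (the
  # second haplotypes, which carry no heterozygous alternative) is exactly
  # the between-site list
  for (cn in names(g$genome)) {
    d <- brute_diff(as.character(ind$individuals[[1]]$hap2[[cn]]),
                    as.character(ind$individuals[[2]]$hap2[[cn]]))
    expect_setequal(d, ind$between$true_pos[ind$between$chrom == cn])
  }
  # within sites: the carrier's haplotypes differ only there
  for (i in 1:2) {
    w <- ind$within[ind$within$individual == i, ]
    for (cn in names(g$genome)) {
      d <- brute_diff(as.character(ind$individuals[[i]]$hap1[[cn]]),
                      as.character(ind$individuals[[i]]$hap2[[cn]]))
      expect_setequal(d, w$true_pos[w$chrom == cn])
    }
  }

  # zero variant sites: both individuals equal the true genome
  cfg0 <- small_config(seed = 17, n_between_sites = 0, n_within_sites = 0)
  ind0 <- simulate_individuals(g, cfg0, truth = inj$truth)
  expect_identical(as.character(ind0$individuals[[1]]$hap1[[1]]),
                   as.character(g$genome[[1]]))
  expect_identical(as.character(ind0$individuals[[2]]$hap2[[1]]),
                   as.character(g$genome[[1]]))
})

test_that("short reads are exact haplotype substrings at zero error, hit the
          target depth, and pair inward at the insert size", {
  cfg <- sim_config(seed = 23, genome_length = 5e4, n_chromosomes = 1,
                    n_genes = 0, n_substitutions = 0,
                    n_small_insertions = 0, n_small_deletions = 0,
                    n_between_sites = 0, n_within_sites = 0,
                    large_insertion_sizes = numeric(0),
                    large_deletion_sizes = numeric(0),
                    error_rate = 0, adapter_contam_rate = 0,
                    q_tail_frac = 0, depth = 40)
  g <- simulate_genome(cfg)
  ind <- simulate_individuals(g, cfg)$individuals[[1]]

  rd <- simulate_short_reads(ind, cfg, paired = FALSE, read_length = 50)
  hap <- as.character(ind$hap1[[1]])
  for (i in sample(nrow(rd), 25)) {
    expect_true(grepl(rd$seq[i], hap, fixed = TRUE) ||
                  grepl(rc_chr(rd$seq[i]), hap, fixed = TRUE))
  }

  # coverage oracle from the recorded fragment origins
  tr <- attr(rd, "truth")
  cov <- IRanges::coverage(IRanges::IRanges(tr$start, width = 50))
  expect_lt(abs(mean(cov[1:5e4]) - 40) / 40, 0.05)

  # paired mode: inward orientation, span ~ insert
  rp <- simulate_short_reads(ind, cfg, paired = TRUE, read_length = 76)
  trp <- attr(rp, "truth")
  m1 <- rp[rp$mate == "mate1", ][1:200, ]
  m2 <- rp[rp$mate == "mate2", ][1:200, ]
  for (i in 1:50) {
    # one mate forward, one the reverse complement of the fragment end
    frag <- substring(as.character(ind$hap1[[1]]),
                      trp$start[i], trp$start[i] + trp$insert[i] - 1L)
    fr <- if (trp$hap[i] == 2)
      substring(as.character(ind$hap2[[1]]),
                trp$start[i], trp$start[i] + trp$insert[i] - 1L) else frag
    s1 <- m1$seq[i]; s2 <- m2$seq[i]
    fwd <- substr(fr, 1, 76)
    rev <- rc_chr(substr(fr, nchar(fr) - 75, nchar(fr)))
    expect_true((s1 == fwd && s2 == rev) || (s1 == rev && s2 == fwd))
  }
  expect_lt(abs(mean(trp$insert) - cfg$insert_mean), 2)
})

test_that("long reads average ~377 bp and are exact substrings at zero
          error", {
  cfg <- sim_config(seed = 29, genome_length = 2e5, n_chromosomes = 1,
                    n_genes = 0, n_substitutions = 0,
                    n_small_insertions = 0, n_small_deletions = 0,
                    n_between_sites = 0, n_within_sites = 0,
                    large_insertion_sizes = numeric(0),
                    large_deletion_sizes = numeric(0),
                    long_read_error = 0, long_read_depth = 6)
  g <- simulate_genome(cfg)
  ind <- simulate_individuals(g, cfg)$individuals[[1]]
  lr <- simulate_long_reads(ind, cfg)
  # published average read length, stochastic tolerance 5%
  expect_lt(abs(mean(nchar(lr$seq)) - 377) / 377, 0.05)
  hap <- as.character(ind$hap1[[1]])
  for (i in sample(nrow(lr), 20)) {
    expect_true(grepl(lr$seq[i], hap, fixed = TRUE) ||
                  grepl(rc_chr(lr$seq[i]), hap, fixed = TRUE))
  }
})

test_that("simulated optical maps degrade the exact digest as configured", {
  cfg0 <- sim_config(seed = 31, genome_length = 3e5, n_chromosomes = 1,
                     n_genes = 0, optical_cv = 0, missing_cut_prob = 0,
                     extra_cut_prob = 0, min_fragment = 0,
                     large_insertion_sizes = numeric(0))
  g <- simulate_genome(cfg0)
  dig <- digest_in_silico(as.character(g$genome[[1]]), map_id = "chr1")

  # all noise terms zero: output equals the exact digest
  om0 <- simulate_optical_map(g$genome, cfg0)
  expect_equal(om0[[1]]$fragments, dig$fragments)
  expect_equal(sum(om0[[1]]$fragments), 3e5)

  # missing-cut probability 1: a single fragment the length of the molecule
  cfg1 <- sim_config(seed = 31, genome_length = 3e5, n_chromosomes = 1,
                     n_genes = 0, optical_cv = 0, missing_cut_prob = 1,
                     extra_cut_prob = 0, min_fragment = 0,
                     large_insertion_sizes = numeric(0))
  om1 <- simulate_optical_map(g$genome, cfg1)
  expect_equal(om1[[1]]$fragments, 3e5)

  # sizing noise: empirical relative-error sd within 20% of the configured
  # cv at n = 1000 fragments (constructed molecule with 1000 cut sites)
  set.seed(37)
  units <- vapply(1:1000, function(i)
    paste0(paste(sample(c("A", "C", "G", "T"), 992, TRUE), collapse = ""),
           "ATTTAAAT"), character(1))
  mol <- c(mol1 = paste(units, collapse = ""))
  dig <- digest_in_silico(mol[[1]], map_id = "mol1")
  cfgcv <- sim_config(seed = 37, optical_cv = 0.05, missing_cut_prob = 0,
                      extra_cut_prob = 0, min_fragment = 0)
  omcv <- simulate_optical_map(mol, cfgcv)
  expect_equal(length(omcv[[1]]$fragments), length(dig$fragments))
  relerr <- (omcv[[1]]$fragments - dig$fragments) / dig$fragments
  expect_lt(abs(sd(relerr) - 0.05) / 0.05, 0.2)
})
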