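# Fixture builders shared across test files. Everything is generated in code
# at test time; no stored data.

# Minimal site_calls object from a per-site specification data frame with
# columns ref_n, alt_n (support of one alternative base), alt (its base) and
# depth (defaults to ref_n + alt_n). Reference base fixed to "A".
make_site_calls <- function(spec, min_depth = 10, ref_frac = 0.8,
                            allele_frac = 0.4) {
  n <- nrow(spec)
  depth <- if (!is.null(spec[["depth"]])) spec[["depth"]] else
    spec$ref_n + spec$alt_n
  alt <- if (!is.null(spec[["alt"]])) spec[["alt"]] else rep("C", n)
  counts <- matrix(0L, 5, n, dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  counts["A", ] <- spec$ref_n
  for (i in seq_len(n)) if (spec$alt_n[i] > 0)
    counts[alt[i], i] <- spec$alt_n[i]
  counts["N", ] <- depth - colSums(counts)
  pil <- structure(list(
    counts = list(chr1 = counts),
    indels = data.frame(chrom = character(0), anchor = integer(0),
                        type = character(0), len = integer(0),
                        seq = character(0), count = integer(0)),
    ref = c(chr1 = strrep("A", n))), class = "pileup")
  classify_sites(pil, min_depth, ref_frac, allele_frac)
}

# Pileup with a single indel allele at a given anchor over a uniform-depth
# background (for the small-indel caller examples).
make_indel_pileup <- function(depth, support, type, len, anchor = 50L,
                              L = 100L) {
  counts <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  counts["A", ] <- depth
  structure(list(
    counts = list(chr1 = counts),
    indels = data.frame(chrom = "chr1", anchor = anchor, type = type,
                        len = len, seq = strrep("G", len), count = support),
    ref = c(chr1 = strrep("A", L))), class = "pileup")
}

# A small simulated study shared by the heavier integration tests.
small_config <- function(seed = 11, ...) {
  args <- list(seed = seed, genome_length = 1.2e5, n_chromosomes = 2,
               n_genes = 6, n_substitutions = 12, n_small_insertions = 4,
               n_small_deletions = 4, n_between_sites = 5, n_within_sites = 5,
               large_insertion_sizes = numeric(0),
               large_deletion_sizes = numeric(0))
  do.call(sim_config, utils::modifyList(args, list(...)))
}
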