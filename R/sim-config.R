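#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults describe the stated desk-scale world used throughout the
#' package tests: a 1 Mb diploid-ish genome re-sequenced in two individuals
#' at 20x each (40x pooled), short reads with 0.5% per-base error, long reads
#' averaging 377 bp, and an optical map with 5% fragment sizing error and 2%
#' cut errors.
#'
#' Error/variant type naming follows the correction action on the assembly:
#' an \emph{insertion} error means the assembly lacks bases that the true
#' genome (and hence every read) carries, so correcting it inserts bases and
#' lengthens the assembly; a \emph{deletion} error means the assembly carries
#' extra bases, so correcting it deletes them.
#'
#' @param seed Integer RNG seed. Mandatory: every generator derives all of its
#'   randomness from it.
#' @param genome_length Total genome length in bp, split across chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param gc_fraction Genome GC content in `[0, 1]`.
#' @param repeat_fraction Fraction of the genome covered by exact repeat
#'   copies (dispersed duplicates of sampled units).
#' @param repeat_unit_range Length range (bp) of repeat units.
#' @param n_genes Number of simulated gene models.
#' @param n_substitutions,n_small_insertions,n_small_deletions Counts of
#'   injected assembly errors (small indels are 1-4 bp).
#' @param large_insertion_sizes,large_deletion_sizes Sizes (bp, each >= 100)
#'   of injected large assembly errors; one event per element.
#' @param n_between_sites Homozygous differences between the two individuals.
#' @param n_within_sites Heterozygous sites, each in exactly one individual.
#' @param read_length Paired-end read length (bp) for the second individual's
#'   library.
#' @param se_read_length Single-end read length (bp) for the first
#'   individual's library.
#' @param paired Whether the second individual's library is paired-end.
#' @param insert_mean,insert_sd Paired-end insert size model (bp).
#' @param depth Target per-individual depth of coverage (x).
#' @param error_rate Per-base substitution error rate of short reads.
#' @param adapters Adapter sequences subject to read-through/contamination
#'   and removed during preprocessing.
#' @param adapter_contam_rate Fraction of reads carrying a 3' adapter run-in.
#' @param q_high Baseline Phred quality of simulated bases.
#' @param q_tail_frac Probability that a read end carries a low-quality tail.
#' @param q_tail_geom Geometric parameter of tail lengths.
#' @param long_read_mean Mean long-read length (bp); default 377.
#' @param long_read_shape Gamma shape of the long-read length distribution.
#' @param long_read_min Minimum long-read length (bp).
#' @param long_read_depth Long-read depth of coverage (x).
#' @param long_read_error Per-base substitution error rate of long reads.
#' @param optical_cv Coefficient of variation of optical fragment sizing.
#' @param missing_cut_prob Probability that a true cut is missed (fragments
#'   merge).
#' @param extra_cut_prob Per-fragment probability of a spurious extra cut.
#' @param min_fragment Minimum detectable optical fragment (bp); smaller
#'   fragments are lost (desorption). 0 disables.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 1e6,
                       n_chromosomes = 2,
                       gc_fraction = 0.44,
                       repeat_fraction = 0.10,
                       repeat_unit_range = c(200, 2000),
                       n_genes = 40,
                       n_substitutions = 100,
                       n_small_insertions = 25,
                       n_small_deletions = 25,
                       large_insertion_sizes = 200,
                       large_deletion_sizes = 500,
                       n_between_sites = 20,
                       n_within_sites = 20,
                       read_length = 76,
                       se_read_length = 51,
                       paired = TRUE,
                       insert_mean = 150,
                       insert_sd = 15,
                       depth = 20,
                       error_rate = 0.005,
                       adapters = c(
                         "GATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                         "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"),
                       adapter_contam_rate = 0.02,
                       q_high = 38,
                       q_tail_frac = 0.15,
                       q_tail_geom = 0.4,
                       long_read_mean = 377,
                       long_read_shape = 4,
                       long_read_min = 50,
                       long_read_depth = 5,
                       long_read_error = 0.005,
                       optical_cv = 0.05,
                       missing_cut_prob = 0.02,
                       extra_cut_prob = 0.02,
                       min_fragment = 1200) {
  if (missing(seed)) stop("'seed' is a mandatory field of sim_config()")
  cfg <- as.list(environment())
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    genome_length >= 1000, n_chromosomes >= 1,
    gc_fraction >= 0, gc_fraction <= 1,
    repeat_fraction >= 0, repeat_fraction < 1,
    length(repeat_unit_range) == 2, repeat_unit_range[1] >= 10,
    n_genes >= 0,
    n_substitutions >= 0, n_small_insertions >= 0, n_small_deletions >= 0,
    all(large_insertion_sizes >= 100 | length(large_insertion_sizes) == 0),
    all(large_deletion_sizes >= 100 | length(large_deletion_sizes) == 0),
    n_between_sites >= 0, n_within_sites >= 0,
    read_length >= 32, se_read_length >= 32,
    insert_mean > 0, insert_sd >= 0,
    depth > 0,
    error_rate >= 0, error_rate <= 1,
    adapter_contam_rate >= 0, adapter_contam_rate <= 1,
    q_high >= 2, q_high <= 41,
    q_tail_frac >= 0, q_tail_frac <= 1,
    q_tail_geom > 0, q_tail_geom <= 1,
    long_read_mean > 0, long_read_shape > 0, long_read_min > 0,
    long_read_depth > 0,
    long_read_error >= 0, long_read_error <= 1,
    optical_cv >= 0,
    missing_cut_prob >= 0, missing_cut_prob <= 1,
    extra_cut_prob >= 0, extra_cut_prob <= 1,
    min_fragment >= 0
  )
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length / 1e6, "Mb genome,", x$n_chromosomes,
      "chromosomes, seed", x$seed, "\n")
  cat("  assembly errors:", x$n_substitutions, "subs,",
      x$n_small_insertions, "+", x$n_small_deletions, "small indels,",
      length(x$large_insertion_sizes) + length(x$large_deletion_sizes),
      "large events\n")
  cat("  alleles:", x$n_between_sites, "between,", x$n_within_sites,
      "within\n")
  cat("  short reads:", x$depth, "x per individual, error", x$error_rate,
      "\n")
  invisible(x)
}
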