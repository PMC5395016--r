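# End-to-end orchestration over a simulated study, and evaluation of the
# classifier's calls against the simulator's ground truth.

#' Run the short-read error-detection pipeline on a simulated study
#'
#' Preprocesses both individuals' reads, maps them to the assembly, filters
#' to uniquely mapped records with mapping confidence >= 20, builds the two
#' individual pileups and their pooled union, classifies every site per
#' dataset (R/N/A/L), combines the three classifications into the five
#' genotype classes, and calls 1-4 bp indel errors from the pooled pileup.
#'
#' @param sim A [simulate_study()] result.
#' @param min_depth,ref_frac,allele_frac Classification thresholds.
#' @param min_confidence Mapping confidence cutoff.
#' @return List with prep stats, filtered records, the three pileups and
#'   site_calls, `combined` calls, `snp_errors`, `indels` (errors +
#'   allelic), `allelic_snps`, and the coverage profile of the pooled
#'   pileup.
#' @export
run_pipeline <- function(sim, min_depth = 10, ref_frac = 0.8,
                         allele_frac = 0.4, min_confidence = 20) {
  cfg <- sim$config
  prep1 <- preprocess_reads(sim$reads1, cfg$adapters)
  prep2 <- preprocess_reads(sim$reads2, cfg$adapters)

  rec1 <- filter_alignments(map_reads(prep1$reads, sim$assembly),
                            min_confidence)
  rec2 <- filter_alignments(map_reads(prep2$reads, sim$assembly),
                            min_confidence)
  p1 <- build_pileup(rec1, sim$assembly)
  p2 <- build_pileup(rec2, sim$assembly)
  pp <- merge_pileups(p1, p2)

  c1 <- classify_sites(p1, min_depth, ref_frac, allele_frac)
  c2 <- classify_sites(p2, min_depth, ref_frac, allele_frac)
  cp <- classify_sites(pp, min_depth, ref_frac, allele_frac)
  comb <- combine_datasets(c1, c2, cp)
  indels <- call_small_indels(pp, min_depth, ref_frac, allele_frac,
                              records = rbind(rec1, rec2))
  snp_err <- snp_error_records(comb, cp)

  list(prep = list(ind1 = prep1$stats, ind2 = prep2$stats),
       records = list(ind1 = rec1, ind2 = rec2),
       pileups = list(ind1 = p1, ind2 = p2, pooled = pp),
       site_calls = list(ind1 = c1, ind2 = c2, pooled = cp),
       combined = comb,
       snp_errors = snp_err,
       indels = indels,
       allelic_snps = allelic_sites(comb, cp),
       coverage = coverage_profile(pp))
}

#' Evaluate recovery of the injected truth
#'
#' Compares pipeline calls against the simulator's truth table, per class.
#' Sensitivity is measured over \emph{effective} truth sites -- pooled depth
#' >= `min_depth`, and for the allele classes also per-individual depth >=
#' `min_depth` -- matching the pipeline's own assessability rule (sites
#' below the depth floor are declared low-depth by construction, not
#' missed). Precision is measured over all calls of the class. Substitution
#' errors and small indels match by exact position (indels also by type and
#' size); allele classes match by assembly position and class.
#'
#' @param pipe A [run_pipeline()] result.
#' @param truth The study truth table.
#' @param min_depth Effective-site depth floor.
#' @return Data frame: class, n_truth, n_effective, n_called, true_positive,
#'   sensitivity (over effective sites), precision.
#' @export
evaluate_recovery <- function(pipe, truth, min_depth = 10) {
  dep_p <- pileup_depth(pipe$pileups$pooled)
  dep_1 <- pileup_depth(pipe$pileups$ind1)
  dep_2 <- pileup_depth(pipe$pileups$ind2)
  dp <- function(dep, chrom, pos) mapply(function(cn, p) {
    d <- dep[[cn]]
    if (is.null(d) || p < 1 || p > length(d)) 0L else d[p]
  }, chrom, pos)

  ae <- truth$assembly_errors
  subs <- ae[ae$type == "substitution", , drop = FALSE]
  smi <- ae[ae$type %in% c("insertion", "deletion"), , drop = FALSE]
  btw <- truth$between_individual_sites
  wth <- truth$within_individual_sites

  key <- function(chrom, pos) paste(chrom, pos)
  ikey <- function(chrom, pos, type, size) paste(chrom, pos, type, size)

  rows <- list()

  # substitution errors
  eff <- dp(dep_p, subs$chrom, subs$position) >= min_depth
  called <- pipe$snp_errors
  tp <- sum(key(subs$chrom, subs$position)[eff] %in%
              key(called$chrom, called$position))
  rows$sequencing_error_snp <- data.frame(
    class = "sequencing_error_snp", n_truth = nrow(subs),
    n_effective = sum(eff), n_called = nrow(called), true_positive = tp,
    sensitivity = tp / max(sum(eff), 1),
    precision = sum(key(called$chrom, called$position) %in%
                      key(subs$chrom, subs$position)) /
      max(nrow(called), 1))

  # small indel errors
  eff <- dp(dep_p, smi$chrom, smi$position) >= min_depth
  called <- pipe$indels$errors
  tkey <- ikey(smi$chrom, smi$position, smi$type, smi$size)
  ckey <- ikey(called$chrom, called$position, called$type, called$size)
  tp <- sum(tkey[eff] %in% ckey)
  rows$sequencing_error_indel <- data.frame(
    class = "sequencing_error_indel", n_truth = nrow(smi),
    n_effective = sum(eff), n_called = nrow(called), true_positive = tp,
    sensitivity = tp / max(sum(eff), 1),
    precision = sum(ckey %in% tkey) / max(nrow(called), 1))

  # allele classes from the combined calls
  comb_class <- function(chrom, pos) mapply(function(cn, p) {
    cc <- pipe$combined$combined[[cn]]
    if (is.null(cc) || p < 1 || p > nrow(cc)) NA_character_ else cc$class[p]
  }, chrom, pos)
  all_called <- do.call(rbind, lapply(names(pipe$combined$combined),
    function(cn) {
      cc <- pipe$combined$combined[[cn]]
      sel <- which(cc$class %in% c("allele_within", "allele_between"))
      if (!length(sel)) return(NULL)
      data.frame(chrom = cn, pos = sel, class = cc$class[sel])
    }))
  if (is.null(all_called))
    all_called <- data.frame(chrom = character(0), pos = integer(0),
                             class = character(0))

  for (cls in c("allele_between", "allele_within")) {
    tr <- if (cls == "allele_between") btw else wth
    eff <- dp(dep_p, tr$chrom, tr$assembly_pos) >= min_depth &
      dp(dep_1, tr$chrom, tr$assembly_pos) >= min_depth &
      dp(dep_2, tr$chrom, tr$assembly_pos) >= min_depth
    got <- comb_class(tr$chrom, tr$assembly_pos)
    tp <- sum(eff & !is.na(got) & got == cls)
    called <- all_called[all_called$class == cls, , drop = FALSE]
    rows[[cls]] <- data.frame(
      class = cls, n_truth = nrow(tr), n_effective = sum(eff),
      n_called = nrow(called), true_positive = tp,
      sensitivity = tp / max(sum(eff), 1),
      precision = sum(key(called$chrom, called$pos) %in%
                        key(tr$chrom, tr$assembly_pos)) /
        max(nrow(called), 1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collect all error records of a pipeline run
#'
#' Concatenates SNP-type and indel-type error records into the input
#' expected by [apply_corrections()], sorted and de-conflicted: when records
#' overlap (typically a substitution call at the edge of an indel event,
#' where the gapped columns distort base frequencies), the indel record is
#' kept and the shadowed record dropped, so the result is always applicable.
#'
#' @param pipe A [run_pipeline()] result.
#' @param large_events Optional corroborated split-read events
#'   ([corroborate_events()]) to include as large indel records (with
#'   placeholder "." alleles: the inserted sequence is known only from the
#'   supporting reads, which is reporting detail, not needed for
#'   accounting).
#' @return Error-record data frame.
#' @export
collect_error_records <- function(pipe, large_events = NULL) {
  er <- rbind(pipe$snp_errors,
              pipe$indels$errors[, c("chrom", "position", "type",
                                     "ref_allele", "corrected_allele",
                                     "size")])
  if (!is.null(large_events) && nrow(large_events) > 0L) {
    le <- data.frame(chrom = large_events$chrom,
                     position = large_events$breakpoint,
                     type = paste0("large_", large_events$event_type),
                     ref_allele = ".", corrected_allele = ".",
                     size = as.integer(round(large_events$size)))
    er <- rbind(er, le)
  }
  # resolve overlaps: indel records take precedence over snp records; among
  # equal priority the leftmost wins
  prio <- ifelse(er$type == "snp", 2L, 1L)
  er <- er[order(er$chrom, er$position, prio), , drop = FALSE]
  span_end <- er$position + ifelse(grepl("deletion", er$type), er$size, 1L)
  keep <- rep(FALSE, nrow(er))
  last_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(er))) {
    if (er$chrom[i] != last_chrom || er$position[i] > last_end) {
      keep[i] <- TRUE
      last_chrom <- er$chrom[i]
      last_end <- span_end[i]
    }
  }
  er <- er[keep, , drop = FALSE]
  rownames(er) <- NULL
  er
}
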