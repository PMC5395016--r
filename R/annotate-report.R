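# Effect annotation of allelic SNPs, assembly correction with coordinate
# liftover, gap placeholders, and assembly/genome-size/rate accounting.

severity_order <- c("Nonsense", "Missense", "Silent", "UTR", "Intron",
                    "Intergenic")

#' Annotate the effect of substitution sites on gene models
#'
#' Classifies each biallelic substitution site into one of six groups --
#' Nonsense, Missense, Silent, UTR, Intron, Intergenic -- by interval
#' containment against the gene models and, for coding sites, by codon
#' substitution with strand-aware complementation. Start-loss and stop-loss
#' changes fold into Missense and splice-region changes into Intron (the
#' six-way scheme has no finer classes). The site-level effect is the most
#' severe across overlapping transcripts, in the order listed.
#'
#' @param sites Data frame with chrom, pos, ref, alt (substitutions only),
#'   in the coordinates of `genome`.
#' @param gene_models Feature data frame (as from [simulate_genome()] /
#'   [read_gff3()]).
#' @param genome Sequences the gene models refer to.
#' @param codon_table Named vector mapping codons to amino acids
#'   (default [Biostrings::GENETIC_CODE]).
#' @return The sites data frame with `effect` (site level) and
#'   `transcripts` (comma-separated per-transcript detail) columns.
#' @export
annotate_effect <- function(sites, gene_models, genome,
                            codon_table = Biostrings::GENETIC_CODE) {
  seqs <- as_chrom_character(genome)
  g <- gene_models
  tx <- g[g$type == "mRNA", , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

  effect_in_tx <- function(chrom, pos, ref, alt, tid) {
    feats <- g[!is.na(g$parent) & g$parent == tid, , drop = FALSE]
    cds <- feats[feats$type == "CDS", , drop = FALSE]
    exon <- feats[feats$type == "exon", , drop = FALSE]
    strand <- tx$strand[tx$id == tid][1]
    in_cds <- any(pos >= cds$start & pos <= cds$end)
    if (in_cds) {
      # CDS-local coordinate in transcription order
      cds <- cds[order(cds$start, decreasing = (strand == "-")), ,
                 drop = FALSE]
      total <- sum(cds$end - cds$start + 1L)
      if (total %% 3L != 0L)
        stop("invalid frame: CDS length of ", tid, " not divisible by 3")
      off <- 0L; cpos <- NA_integer_
      for (r in seq_len(nrow(cds))) {
        if (pos >= cds$start[r] && pos <= cds$end[r]) {
          cpos <- off + if (strand == "+") pos - cds$start[r] + 1L
                        else cds$end[r] - pos + 1L
          break
        }
        off <- off + cds$end[r] - cds$start[r] + 1L
      }
      # coding-strand alleles
      cref <- if (strand == "+") ref else comp[[ref]]
      calt <- if (strand == "+") alt else comp[[alt]]
      codon_i <- (cpos - 1L) %/% 3L
      within <- (cpos - 1L) %% 3L + 1L
      # assemble the coding sequence: concatenate exon pieces in genomic
      # order, then reverse-complement the whole for minus-strand genes
      inc <- cds[order(cds$start), , drop = FALSE]
      cds_seq <- paste(vapply(seq_len(nrow(inc)), function(r)
        substr(seqs[[chrom]], inc$start[r], inc$end[r]), character(1)),
        collapse = "")
      if (strand == "-") cds_seq <- revcomp(cds_seq)
      codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      stopifnot(substr(codon, within, within) == cref)
      alt_codon <- codon
      substr(alt_codon, within, within) <- calt
      aa_ref <- codon_table[[codon]]
      aa_alt <- codon_table[[alt_codon]]
      if (aa_ref == aa_alt) return("Silent")
      if (aa_alt == "*") return("Nonsense")
      return("Missense")
    }
    if (any(pos >= exon$start & pos <= exon$end)) return("UTR")
    "Intron"
  }

  n <- nrow(sites)
  effect <- character(n); detail <- character(n)
  for (i in seq_len(n)) {
    hit <- tx[tx$chrom == sites$chrom[i] & sites$pos[i] >= tx$start &
                sites$pos[i] <= tx$end, , drop = FALSE]
    if (nrow(hit) == 0L) {
      effect[i] <- "Intergenic"; detail[i] <- ""
      next
    }
    effs <- vapply(hit$id, function(tid)
      effect_in_tx(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i],
                   tid), character(1))
    effect[i] <- severity_order[min(match(effs, severity_order))]
    detail[i] <- paste(hit$id, effs, sep = ":", collapse = ",")
  }
  sites$effect <- effect
  sites$transcripts <- detail
  sites
}

#' Apply error corrections to the assembly
#'
#' Applies substitution, insertion and deletion error records (see
#' [sim_config()] for the correction-action naming: insertion records insert
#' the missing bases after their anchor and lengthen the assembly; deletion
#' records remove the extra bases following their anchor). Returns the
#' corrected assembly and a coordinate offset map for lifting positions
#' between the old and new frames.
#'
#' @param assembly Reference sequences.
#' @param error_records Data frame with chrom, position, type
#'   (snp/insertion/deletion, large_ prefixes allowed), ref_allele,
#'   corrected_allele, size. Records must not overlap.
#' @return List with `assembly` (corrected DNAStringSet) and `offset_map`
#'   (chrom, old_pos, new_pos, delta) usable with [lift_coordinate()].
#' @export
apply_corrections <- function(assembly, error_records) {
  genome <- as_dnastringset(assembly)
  er <- error_records
  if (nrow(er) == 0L)
    return(list(assembly = genome,
                offset_map = data.frame(chrom = character(0),
                                        old_start = integer(0),
                                        old_end = integer(0),
                                        delta = integer(0))))
  er <- er[order(er$chrom, er$position), , drop = FALSE]
  type <- sub("^large_", "", er$type)
  type[type == "substitution"] <- "snp"
  stopifnot(all(type %in% c("snp", "insertion", "deletion")))
  # affected old-coordinate interval per record
  at_start <- ifelse(type == "snp", er$position, er$position + 1L)
  at_end <- ifelse(type == "deletion", er$position + er$size, er$position)
  at_end <- ifelse(type == "snp", er$position, at_end)
  value <- ifelse(type == "deletion", "", er$corrected_allele)
  # overlap check within chromosome
  for (cn in unique(er$chrom)) {
    sel <- er$chrom == cn
    s <- at_start[sel]; e <- pmax(at_end[sel], at_start[sel])
    if (any(s[-1] <= e[-length(e)]))
      stop("overlapping correction records on ", cn, ": positions ",
           paste(er$position[sel][c(FALSE, s[-1] <= e[-length(e)])],
                 collapse = ", "))
  }
  out <- genome
  for (cn in names(genome)) {
    sel <- which(er$chrom == cn)
    if (!length(sel)) next
    out[[cn]] <- Biostrings::replaceAt(
      out[[cn]], IRanges::IRanges(at_start[sel], at_end[sel]),
      as.character(value[sel]))
  }
  delta <- nchar(value) - (at_end - at_start + 1L)
  offset_map <- data.frame(chrom = er$chrom, old_start = at_start,
                           old_end = pmax(at_end, at_start - 1L),
                           delta = delta)
  list(assembly = out, offset_map = offset_map)
}

#' Lift a coordinate across an assembly correction
#'
#' Maps positions between the uncorrected and corrected coordinate frames
#' using the offset map from [apply_corrections()]. Positions outside
#' corrected intervals map exactly; a position inside a removed interval maps
#' to the base preceding it.
#'
#' @param offset_map From [apply_corrections()].
#' @param chrom,pos Vectors of positions.
#' @param direction `"old_to_new"` or `"new_to_old"`.
#' @return Integer vector of lifted positions.
#' @export
lift_coordinate <- function(offset_map, chrom, pos,
                            direction = c("old_to_new", "new_to_old")) {
  direction <- match.arg(direction)
  om <- offset_map[order(offset_map$chrom, offset_map$old_start), ,
                   drop = FALSE]
  vapply(seq_along(pos), function(i) {
    e <- om[om$chrom == chrom[i], , drop = FALSE]
    if (nrow(e) == 0L) return(as.integer(pos[i]))
    if (direction == "old_to_new") {
      before <- e$old_end < pos[i]
      inside <- !before & e$old_start <= pos[i]
      p <- pos[i] + sum(e$delta[before])
      if (any(inside)) {
        # position removed/replaced: snap to the last surviving base before it
        k <- which(inside)[1]
        p <- e$old_start[k] - 1L + sum(e$delta[before])
      }
      as.integer(p)
    } else {
      # invert: new interval starts shift cumulatively
      shift <- 0L
      for (k in seq_len(nrow(e))) {
        new_end <- e$old_end[k] + shift + e$delta[k]
        if (pos[i] > new_end) shift <- shift + e$delta[k] else break
      }
      as.integer(pos[i] - shift)
    }
  }, integer(1))
}

#' Insert gap placeholders
#'
#' Inserts a run of 1,000 Ns at each physical gap coordinate and N runs at
#' annotated telomeric chromosome ends.
#'
#' @param assembly Reference sequences.
#' @param gap_annotations Data frame with chrom, pos (base after which the
#'   gap lies; ignored for telomeres) and type (`"physical"`,
#'   `"telomere_start"`, `"telomere_end"`).
#' @param n_gap Placeholder length (default 1000; the telomeric run length is
#'   not separately published and uses the same default).
#' @return DNAStringSet with placeholders inserted.
#' @export
insert_gap_placeholders <- function(assembly, gap_annotations, n_gap = 1000L) {
  genome <- as_dnastringset(assembly)
  if (is.null(gap_annotations) || nrow(gap_annotations) == 0L) return(genome)
  run <- strrep("N", n_gap)
  for (cn in unique(gap_annotations$chrom)) {
    ga <- gap_annotations[gap_annotations$chrom == cn, , drop = FALSE]
    L <- Biostrings::width(genome[cn])
    pos <- ifelse(ga$type == "physical", ga$pos,
                  ifelse(ga$type == "telomere_start", 0L, L))
    ga <- ga[order(pos, decreasing = TRUE), , drop = FALSE]
    pos <- sort(pos, decreasing = TRUE)
    for (p in pos) {
      genome[[cn]] <- Biostrings::replaceAt(
        genome[[cn]], IRanges::IRanges(p + 1L, p), run)
    }
  }
  genome
}

#' Assembly and genome-size accounting
#'
#' Computes the accounting identities of an assembly release: total assembly
#' size per gap-estimate source (sequence length plus the summed gap
#' estimates), estimated genome size (total plus the rDNA allowance, which
#' optical/FISH gap estimates do not capture), and the coverage fraction
#' (sequence length over estimated genome size). Genome sizes are reported
#' in Mbp at 1 decimal and coverage as a percentage at 1 decimal.
#'
#' @param sequence_length Assembled sequence length (bp).
#' @param gap_estimates Named numeric vector of summed gap sizes per source,
#'   e.g. `c(cytological = ..., optical = ...)`.
#' @param rdna_bp rDNA allowance in bp (default 3.7e6).
#' @return An `assembly_account` list: per-source totals, genome sizes (bp
#'   and Mbp), coverage percentages, and their min-max ranges.
#' @export
account_assembly <- function(sequence_length, gap_estimates, rdna_bp = 3.7e6) {
  stopifnot(length(gap_estimates) >= 1)
  total <- sequence_length + gap_estimates
  genome_size <- total + rdna_bp
  coverage <- round(sequence_length / genome_size * 100, 1)
  out <- list(
    sequence_length = sequence_length,
    gap_estimates = gap_estimates,
    rdna_bp = rdna_bp,
    total_assembly = total,
    genome_size_bp = genome_size,
    genome_size_mbp = round(genome_size / 1e6, 1),
    coverage_pct = coverage,
    genome_size_range_mbp = round(range(genome_size) / 1e6, 1),
    coverage_range_pct = round(range(sequence_length / genome_size * 100), 1))
  class(out) <- "assembly_account"
  out
}

#' @export
print.assembly_account <- function(x, ...) {
  cat("assembly accounting:\n")
  cat("  sequence length:", format(x$sequence_length, big.mark = ","), "bp\n")
  for (nm in names(x$total_assembly))
    cat(sprintf("  total assembly (%s): %s bp\n", nm,
                format(x$total_assembly[[nm]], big.mark = ",")))
  cat("  genome size:", paste(x$genome_size_range_mbp, collapse = "-"),
      "Mbp\n")
  cat("  coverage:", paste(sort(x$coverage_range_pct), collapse = "-"),
      "%\n")
  invisible(x)
}

#' Sequencing yield in Gbp
#'
#' @param n_reads Read counts per library.
#' @param read_length Read lengths (bp) per library.
#' @return Total yield in Gbp at 1 decimal.
#' @export
read_yield_gbp <- function(n_reads, read_length) {
  round(sum(as.numeric(n_reads) * as.numeric(read_length)) / 1e9, 1)
}

#' Error-count composition
#'
#' @param snp,insertion,deletion Counts of SNP-type, insertion-type and
#'   deletion-type sequencing errors.
#' @return Named vector with the three counts and their total.
#' @export
error_composition <- function(snp, insertion, deletion) {
  c(snp = snp, insertion = insertion, deletion = deletion,
    total = snp + insertion + deletion)
}

#' Summarise a pipeline run
#'
#' Builds the report bundle: preprocessing stage counts with percentages of
#' stage input, mapping placement counts, per-chromosome coverage/effective
#' sites, per-chromosome error/allele rates per 10 kb, error composition and
#' effect-class breakdown. All components are optional; missing inputs give
#' empty/zero tables.
#'
#' @param prep_stats Named list of `prep_stats` (one per library).
#' @param records Alignment records (for placement counts).
#' @param coverage Coverage profile data frame from [coverage_profile()].
#' @param combined A `combined_calls` object.
#' @param indel_errors Indel error records from [call_small_indels()].
#' @param effects Annotated allelic sites from [annotate_effect()].
#' @param min_depth Effective-site depth used for rates (default 10).
#' @return List of data frames: preprocessing, mapping, coverage, rates,
#'   error_composition, effects.
#' @export
summarize_run <- function(prep_stats = NULL, records = NULL, coverage = NULL,
                          combined = NULL, indel_errors = NULL,
                          effects = NULL, min_depth = 10) {
  out <- list()
  if (!is.null(prep_stats)) {
    out$preprocessing <- do.call(rbind, lapply(names(prep_stats), function(nm) {
      s <- prep_stats[[nm]]
      data.frame(library = nm, input = s$input_reads,
                 after_quality_trim = s$after_quality_trim,
                 pct_quality = round(100 * s$after_quality_trim /
                                       max(s$input_reads, 1), 1),
                 after_adapter_trim = s$after_adapter_trim,
                 pct_adapter = round(100 * s$after_adapter_trim /
                                       max(s$input_reads, 1), 1),
                 after_pairing = s$after_pairing,
                 unpaired = s$unpaired_count)
    }))
  }
  if (!is.null(records)) {
    tab <- table(factor(records$placement,
                        levels = c("unique", "multiple", "unmapped")))
    out$mapping <- data.frame(placement = names(tab),
                              reads = as.integer(tab),
                              pct = round(100 * as.integer(tab) /
                                            max(sum(tab), 1), 1))
  }
  if (!is.null(coverage)) out$coverage <- coverage
  if (!is.null(combined)) {
    eff_col <- paste0("cov_ge_", min_depth)
    rates <- do.call(rbind, lapply(names(combined$combined), function(cn) {
      cc <- combined$combined[[cn]]
      eff <- if (!is.null(coverage) && eff_col %in% names(coverage))
        coverage[[eff_col]][coverage$chrom == cn] else sum(cc$class != "low_depth")
      n_err <- sum(cc$class == "sequencing_error")
      n_all <- sum(cc$class %in% c("allele_within", "allele_between"))
      n_btw <- sum(cc$class == "allele_between")
      data.frame(chrom = cn, effective_sites = eff, errors = n_err,
                 error_rate_per10kb = compute_rate(n_err, max(eff, 1)),
                 allelic = n_all,
                 allelic_rate_per10kb = compute_rate(n_all, max(eff, 1)),
                 between = n_btw,
                 between_rate_per10kb = compute_rate(n_btw, max(eff, 1)))
    }))
    out$rates <- rates
    n_snp <- sum(rates$errors)
    n_ins <- if (!is.null(indel_errors))
      sum(indel_errors$type == "insertion") else 0L
    n_del <- if (!is.null(indel_errors))
      sum(indel_errors$type == "deletion") else 0L
    out$error_composition <- error_composition(n_snp, n_ins, n_del)
  }
  if (!is.null(effects)) {
    tab <- table(factor(effects$effect, levels = severity_order))
    out$effects <- data.frame(effect = names(tab), sites = as.integer(tab),
                              pct = round(100 * as.integer(tab) /
                                            max(sum(tab), 1), 1))
  }
  out
}
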