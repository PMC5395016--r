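# Synthetic-data generator: a toy genome with repeats and gene models, an
# erroneous "assembly" derived from it, two re-sequenced individuals, short
# and long reads, and an optical map -- all with recorded ground truth so
# every downstream stage can be tested without external data.

# --- internal placement helpers ---------------------------------------------

# Place an interval of length len on one of the chromosomes, avoiding the
# occupied table occ (data.frame chrom,start,end) with a safety margin.
place_interval <- function(len, chrom_lens, occ, margin = 100L,
                           max_tries = 2000L) {
  for (t in seq_len(max_tries)) {
    ci <- sample.int(length(chrom_lens), 1L, prob = chrom_lens)
    L <- chrom_lens[ci]
    if (L < len + 2L * margin) next
    s <- sample.int(L - len - 2L * margin, 1L) + margin
    cand <- IRanges::IRanges(s - margin, s + len - 1L + margin)
    here <- occ[occ$chrom == names(chrom_lens)[ci], , drop = FALSE]
    if (nrow(here) == 0L ||
        !any(IRanges::overlapsAny(cand, IRanges::IRanges(here$start, here$end))))
      return(list(chrom = names(chrom_lens)[ci], start = s))
  }
  stop("could not place an interval of ", len,
       " bp: insufficient free space (impossible geometry?)")
}

# Sample m single-base sites spread over chromosomes, >= spacing apart,
# outside avoid ranges (data.frame chrom,start,end) and >= end_margin from
# chromosome ends.
sample_sites <- function(m, chrom_lens, spacing = 50L, avoid = NULL,
                         end_margin = 200L, max_tries = 200L) {
  if (m == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  out <- data.frame(chrom = character(0), pos = integer(0))
  for (t in seq_len(max_tries)) {
    need <- m - nrow(out)
    if (need <= 0L) break
    ci <- sample.int(length(chrom_lens), need * 3L, replace = TRUE,
                     prob = chrom_lens)
    pos <- floor(runif(need * 3L, end_margin + 1,
                       chrom_lens[ci] - end_margin)) |> as.integer()
    cand <- data.frame(chrom = names(chrom_lens)[ci], pos = pos)
    for (i in seq_len(nrow(cand))) {
      if (nrow(out) >= m) break
      av <- if (is.null(avoid)) NULL else
        avoid[avoid$chrom == cand$chrom[i], , drop = FALSE]
      if (!is.null(av) && nrow(av) > 0L &&
          any(cand$pos[i] >= av$start & cand$pos[i] <= av$end)) next
      prev <- out$pos[out$chrom == cand$chrom[i]]
      if (length(prev) == 0L || all(abs(cand$pos[i] - prev) >= spacing))
        out <- rbind(out, cand[i, ])
    }
  }
  if (nrow(out) < m)
    stop("insufficient placeable space for ", m, " sites")
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# --- genome ------------------------------------------------------------------

#' Simulate a toy genome with repeats and gene models
#'
#' Generates random chromosome sequences at a given GC content, overlays
#' exact dispersed repeat copies (so that "uniquely mappable" is unambiguous
#' at desk scale), and places non-overlapping gene models with
#' UTR/CDS/intron structure on both strands. CDSs start with ATG, end with a
#' stop codon and contain no internal stops.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` (a
#'   [Biostrings::DNAStringSet] of chromosomes), `genes` (a GFF-like feature
#'   data frame: chrom, type, start, end, strand, phase, id, parent), and
#'   `repeats` (data frame of exact-repeat intervals).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    n_chr <- config$n_chromosomes
    base_len <- floor(config$genome_length / n_chr)
    chrom_lens <- stats::setNames(
      rep(base_len, n_chr) +
        c(rep(0L, n_chr - 1L), config$genome_length - base_len * n_chr),
      paste0("chr", seq_len(n_chr)))
    seqs <- vapply(chrom_lens, random_dna, character(1), gc = config$gc_fraction)

    occ <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    repeats <- occ

    # exact repeat families: two dispersed copies per sampled unit
    target <- config$repeat_fraction * config$genome_length
    placed <- 0
    edits <- list()
    while (placed < target) {
      u <- sample(seq(config$repeat_unit_range[1], config$repeat_unit_range[2]),
                  1L)
      unit <- random_dna(u, config$gc_fraction)
      for (copy in 1:2) {
        loc <- place_interval(u, chrom_lens, occ)
        iv <- data.frame(chrom = loc$chrom, start = loc$start,
                         end = loc$start + u - 1L)
        occ <- rbind(occ, iv)
        repeats <- rbind(repeats, iv)
        edits[[length(edits) + 1L]] <- c(iv, list(value = unit))
      }
      placed <- placed + 2 * u
    }

    # tandem-duplication loci: one S+S locus per requested large insertion
    # error. A large "insertion" (assembly lacking bases) is only split-read
    # detectable when the missing bases duplicate adjacent sequence --
    # otherwise the unaligned novel bases make the >90% read-coverage rule
    # unsatisfiable at ~377 bp read lengths -- so the generator plants the
    # duplication in the true genome and the error injector drops one copy
    # from the assembly. Placed before the gene models because their wide
    # margin needs the largest clear window.
    tandem_sites <- data.frame(chrom = character(0), start = integer(0),
                               size = integer(0))
    for (s in config$large_insertion_sizes) {
      s <- as.integer(s)
      unit <- random_dna(s, config$gc_fraction)
      loc <- place_interval(2L * s, chrom_lens, occ, margin = 5000L)
      occ <- rbind(occ, data.frame(chrom = loc$chrom, start = loc$start,
                                   end = loc$start + 2L * s - 1L))
      edits[[length(edits) + 1L]] <- list(chrom = loc$chrom, start = loc$start,
                                          end = loc$start + 2L * s - 1L,
                                          value = strrep(unit, 2L))
      tandem_sites <- rbind(tandem_sites, data.frame(
        chrom = loc$chrom, start = loc$start, size = s))
    }

    # gene models
    genes <- list()
    for (gi in seq_len(config$n_genes)) {
      g <- build_gene_layout(config)
      if (g$len > max(chrom_lens))
        stop("gene of ", g$len, " bp longer than any chromosome: ",
             "impossible geometry")
      loc <- place_interval(g$len, chrom_lens, occ, margin = 200L)
      occ <- rbind(occ, data.frame(chrom = loc$chrom, start = loc$start,
                                   end = loc$start + g$len - 1L))
      strand <- sample(c("+", "-"), 1L)
      seq_local <- if (strand == "+") g$seq else revcomp(g$seq)
      edits[[length(edits) + 1L]] <- list(chrom = loc$chrom, start = loc$start,
                                          end = loc$start + g$len - 1L,
                                          value = seq_local)
      genes[[gi]] <- gene_features(g, sprintf("gene%03d", gi), loc$chrom,
                                   loc$start, strand)
    }

    # apply overlay edits chromosome by chromosome
    ed <- do.call(rbind, lapply(edits, function(e)
      data.frame(chrom = e$chrom, start = e$start, end = e$end,
                 value = e$value)))
    genome <- Biostrings::DNAStringSet(seqs)
    if (!is.null(ed) && nrow(ed) > 0L) {
      for (cn in names(chrom_lens)) {
        sub <- ed[ed$chrom == cn, , drop = FALSE]
        if (nrow(sub) == 0L) next
        genome[[cn]] <- Biostrings::replaceAt(
          genome[[cn]], IRanges::IRanges(sub$start, sub$end),
          as.character(sub$value))
      }
    }
    gene_df <- if (length(genes)) do.call(rbind, genes) else
      data.frame(chrom = character(0), type = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 phase = integer(0), id = character(0), parent = character(0))
    rownames(gene_df) <- NULL
    list(genome = genome, genes = gene_df, repeats = repeats,
         tandem_sites = tandem_sites)
  })
}

# Sample one gene's internal layout and sense-strand sequence.
build_gene_layout <- function(config) {
  utr5 <- sample(60:150, 1L)
  n_cds <- sample(2:4, 1L)
  cds_lens <- 3L * sample(40:120, n_cds, replace = TRUE)
  introns <- sample(80:300, n_cds - 1L, replace = TRUE)
  utr3 <- sample(100:200, 1L)
  n_codons <- sum(cds_lens) / 3L
  codons <- names(Biostrings::GENETIC_CODE)
  stops <- c("TAA", "TAG", "TGA")
  body <- sample(setdiff(codons, stops), n_codons - 2L, replace = TRUE)
  cds_seq <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
  gc <- config$gc_fraction
  pieces <- character(0)
  cds_off <- cumsum(c(0L, cds_lens))
  for (i in seq_len(n_cds)) {
    pieces <- c(pieces, substr(cds_seq, cds_off[i] + 1L, cds_off[i + 1L]))
    if (i < n_cds) pieces <- c(pieces, random_dna(introns[i], gc))
  }
  seq <- paste0(random_dna(utr5, gc), paste(pieces, collapse = ""),
                random_dna(utr3, gc))
  list(seq = seq, len = nchar(seq), utr5 = utr5, cds_lens = cds_lens,
       introns = introns, utr3 = utr3)
}

# Genomic feature rows for one placed gene.
gene_features <- function(g, id, chrom, gstart, strand) {
  # local sense-strand blocks
  n_cds <- length(g$cds_lens)
  blocks <- list()
  cur <- 1L
  utr5_iv <- c(cur, cur + g$utr5 - 1L); cur <- cur + g$utr5
  cds_iv <- matrix(0L, n_cds, 2)
  for (i in seq_len(n_cds)) {
    cds_iv[i, ] <- c(cur, cur + g$cds_lens[i] - 1L)
    cur <- cur + g$cds_lens[i]
    if (i < n_cds) cur <- cur + g$introns[i]
  }
  utr3_iv <- c(cur, cur + g$utr3 - 1L)
  glen <- g$len
  # exons: first = utr5 + cds1, middles = cds, last = cdsN + utr3
  exon_iv <- cds_iv
  exon_iv[1, 1] <- utr5_iv[1]
  exon_iv[n_cds, 2] <- utr3_iv[2]

  loc2gen <- function(iv) {
    if (strand == "+") c(gstart + iv[1] - 1L, gstart + iv[2] - 1L)
    else c(gstart + glen - iv[2], gstart + glen - iv[1])
  }
  rows <- list()
  add <- function(type, iv, phase = NA_integer_, suffix = "",
                  parent = NA_character_) {
    gv <- loc2gen(iv)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, type = type, start = gv[1], end = gv[2], strand = strand,
      phase = phase, id = paste0(id, suffix), parent = parent)
  }
  add("gene", c(1L, glen))
  add("mRNA", c(1L, glen), suffix = ".1", parent = id)
  for (i in seq_len(n_cds))
    add("exon", exon_iv[i, ], suffix = sprintf(".1.exon%d", i),
        parent = paste0(id, ".1"))
  cum <- 0L
  for (i in seq_len(n_cds)) {
    phase <- (3L - cum %% 3L) %% 3L
    add("CDS", cds_iv[i, ], phase = phase, suffix = ".1.cds",
        parent = paste0(id, ".1"))
    cum <- cum + g$cds_lens[i]
  }
  add("five_prime_UTR", utr5_iv, suffix = ".1.utr5", parent = paste0(id, ".1"))
  add("three_prime_UTR", utr3_iv, suffix = ".1.utr3", parent = paste0(id, ".1"))
  do.call(rbind, rows)
}

# --- assembly errors ---------------------------------------------------------

# Left-normalise an indel call against a reference sequence (1-based anchor =
# base immediately left of the event). Returns list(anchor, seq). Matches the
# pileup engine's normalisation so truth records line up with calls.
normalize_indel <- function(ref, anchor, type, seq) {
  len <- nchar(seq)
  if (type == "ins") {
    while (anchor >= 1L &&
           substr(ref, anchor, anchor) == substr(seq, len, len)) {
      seq <- paste0(substr(seq, len, len), substr(seq, 1L, len - 1L))
      anchor <- anchor - 1L
    }
  } else {
    while (anchor >= 1L &&
           substr(ref, anchor, anchor) == substr(ref, anchor + len, anchor + len)) {
      anchor <- anchor - 1L
    }
    seq <- substr(ref, anchor + 1L, anchor + len)
  }
  list(anchor = anchor, seq = seq)
}

#' Inject assembly errors into the true genome
#'
#' Derives an erroneous "assembly" from the simulated true genome by
#' injecting substitution errors, small (1-4 bp) indel errors and large
#' (>= 100 bp) indel/misassembly events, and records the ground truth.
#' Naming follows the correction action (see [sim_config()]): an `insertion`
#' error is created by \emph{removing} bases from the assembly relative to
#' the true genome (the future caller must insert them back); a `deletion`
#' error is created by \emph{adding} extra bases to the assembly.
#'
#' Errors are placed in non-repeat sequence, >= 50 bp apart (large events
#' >= 10 kb apart, outside genes), and indel truth records are
#' left-normalised against the assembly so they are directly comparable with
#' pileup calls.
#'
#' @param true_genome Result of [simulate_genome()] (or a DNAStringSet, in
#'   which case no repeat/gene masking is available).
#' @param config A [sim_config()] object.
#' @return A list with `assembly` (DNAStringSet) and `truth`, a `truth_table`
#'   list with `assembly_errors` (chrom, position in assembly coordinates,
#'   type, ref_allele, true_allele, size), and `edits` (the true->assembly
#'   coordinate ledger used for liftover).
#' @export
inject_assembly_errors <- function(true_genome, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_dnastringset(if (is.list(true_genome)) true_genome$genome
                            else true_genome)
  repeats <- if (is.list(true_genome)) true_genome$repeats else NULL
  genes <- if (is.list(true_genome)) true_genome$genes else NULL
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))

  with_seed(child_seed(config$seed, 2L), {
    gene_iv <- if (!is.null(genes) && nrow(genes) > 0L) {
      g <- genes[genes$type == "gene", c("chrom", "start", "end")]
      g
    } else NULL
    tandem <- if (is.list(true_genome)) true_genome$tandem_sites else NULL
    tandem_iv <- if (!is.null(tandem) && nrow(tandem) > 0L) data.frame(
      chrom = tandem$chrom, start = tandem$start,
      end = tandem$start + 2L * tandem$size - 1L) else NULL
    avoid_large <- rbind(repeats, gene_iv, tandem_iv)

    li <- as.integer(config$large_insertion_sizes)
    ld <- as.integer(config$large_deletion_sizes)
    if (length(li) > 0L &&
        (is.null(tandem) || nrow(tandem) < length(li) ||
         !all(li %in% tandem$size)))
      stop("large insertion errors require matching tandem-duplication loci ",
           "in the true genome (pass the full simulate_genome() result)")
    large_sites <- sample_sites(length(ld), chrom_lens, spacing = 10000L,
                                avoid = avoid_large, end_margin = 5000L)
    # large insertions: drop the second copy of a planted tandem duplication
    li_sites <- if (length(li) > 0L) {
      ts <- tandem[match(li, tandem$size), , drop = FALSE]
      data.frame(chrom = ts$chrom, pos = ts$start + ts$size - 1L)
    } else data.frame(chrom = character(0), pos = integer(0))
    large_sites <- rbind(
      if (length(ld)) data.frame(chrom = large_sites$chrom,
                                 pos = large_sites$pos) else NULL,
      li_sites)
    large_types <- c(rep("large_deletion", length(ld)),
                     rep("large_insertion", length(li)))
    large_sizes <- c(ld, li)
    n_large <- length(large_sizes)

    large_regions <- if (n_large > 0L) data.frame(
      chrom = large_sites$chrom,
      start = pmax(1L, large_sites$pos - 100L - c(rep(0L, length(ld)), li)),
      end = large_sites$pos + large_sizes + 100L) else NULL

    n_small <- config$n_substitutions + config$n_small_insertions +
      config$n_small_deletions
    small_sites <- sample_sites(n_small, chrom_lens, spacing = 50L,
                                avoid = rbind(repeats, large_regions),
                                end_margin = 200L)
    small_types <- sample(c(rep("substitution", config$n_substitutions),
                            rep("insertion", config$n_small_insertions),
                            rep("deletion", config$n_small_deletions)))

    # edit table in true-genome coordinates:
    #   substitution: at=[pos,pos], value=new base
    #   insertion error (assembly lacks s): at=[pos+1,pos+s], value=""
    #   deletion  error (assembly extra s): at=[pos+1,pos],  value=random(s)
    bases <- c("A", "C", "G", "T")
    ed <- data.frame(chrom = character(0), pos = integer(0), type = character(0),
                     at_start = integer(0), at_end = integer(0),
                     value = character(0), size = integer(0),
                     ref_allele = character(0), true_allele = character(0))
    add_edit <- function(chrom, pos, type, size) {
      true_seq <- as.character(genome[[chrom]])
      if (type == "substitution") {
        old <- substr(true_seq, pos, pos)
        new <- sample(setdiff(bases, old), 1L)
        data.frame(chrom = chrom, pos = pos, type = type,
                   at_start = pos, at_end = pos, value = new, size = 1L,
                   ref_allele = new, true_allele = old)
      } else if (type %in% c("insertion", "large_insertion")) {
        miss <- substr(true_seq, pos + 1L, pos + size)
        data.frame(chrom = chrom, pos = pos, type = type,
                   at_start = pos + 1L, at_end = pos + size, value = "",
                   size = size, ref_allele = "-", true_allele = miss)
      } else {
        extra <- random_dna(size, config$gc_fraction)
        data.frame(chrom = chrom, pos = pos, type = type,
                   at_start = pos + 1L, at_end = pos, value = extra,
                   size = size, ref_allele = extra, true_allele = "-")
      }
    }
    if (n_large > 0L) for (i in seq_len(n_large))
      ed <- rbind(ed, add_edit(large_sites$chrom[i], large_sites$pos[i],
                               large_types[i], large_sizes[i]))
    if (n_small > 0L) for (i in seq_len(n_small)) {
      size <- if (small_types[i] == "substitution") 1L else sample(1:4, 1L)
      ed <- rbind(ed, add_edit(small_sites$chrom[i], small_sites$pos[i],
                               small_types[i], size))
    }

    assembly <- genome
    if (nrow(ed) > 0L) {
      for (cn in names(genome)) {
        sub <- ed[ed$chrom == cn, , drop = FALSE]
        if (nrow(sub) == 0L) next
        assembly[[cn]] <- Biostrings::replaceAt(
          assembly[[cn]], IRanges::IRanges(sub$at_start, sub$at_end),
          as.character(sub$value))
      }
      # assembly coordinates: cumulative shift of preceding edits
      ed <- ed[order(ed$chrom, ed$pos), ]
      ed$delta <- nchar(ed$value) - (ed$at_end - ed$at_start + 1L)
      ed$shift_before <- stats::ave(ed$delta, ed$chrom,
                                    FUN = function(x) cumsum(x) - x)
      ed$assembly_pos <- ed$pos + ed$shift_before
    } else {
      ed$delta <- integer(0); ed$shift_before <- integer(0)
      ed$assembly_pos <- integer(0)
    }

    # truth records in assembly coordinates, indels left-normalised
    recs <- ed
    if (nrow(recs) > 0L) {
      for (i in seq_len(nrow(recs))) {
        if (recs$type[i] == "substitution") next
        aseq <- as.character(assembly[[recs$chrom[i]]])
        if (recs$type[i] %in% c("insertion", "large_insertion")) {
          nn <- normalize_indel(aseq, recs$assembly_pos[i], "ins",
                                recs$true_allele[i])
          recs$assembly_pos[i] <- nn$anchor
          recs$true_allele[i] <- nn$seq
        } else {
          nn <- normalize_indel(aseq, recs$assembly_pos[i], "del",
                                recs$ref_allele[i])
          recs$assembly_pos[i] <- nn$anchor
          recs$ref_allele[i] <- nn$seq
        }
      }
    }
    truth <- list(
      assembly_errors = data.frame(
        chrom = recs$chrom, position = recs$assembly_pos, type = recs$type,
        ref_allele = recs$ref_allele, true_allele = recs$true_allele,
        size = recs$size),
      between_individual_sites = NULL,
      within_individual_sites = NULL,
      edits = ed[, c("chrom", "pos", "assembly_pos", "at_start", "at_end",
                     "delta", "type")]
    )
    class(truth) <- "truth_table"
    list(assembly = assembly, truth = truth)
  })
}

# Lift true-genome positions to assembly coordinates using the edit ledger.
lift_true_to_assembly <- function(truth, chrom, pos) {
  ed <- truth$edits
  vapply(seq_along(pos), function(i) {
    e <- ed[ed$chrom == chrom[i] & ed$at_end < pos[i], , drop = FALSE]
    as.integer(pos[i] + sum(e$delta))
  }, integer(1))
}

# --- individuals -------------------------------------------------------------

#' Simulate two re-sequenced individuals
#'
#' Creates two diploid individuals derived from the true genome: a set of
#' homozygous between-individual differences (one individual carries the
#' true base, the other an alternative, mirroring independently propagated
#' populations) and heterozygous within-individual sites (residual
#' heterozygosity) each carried by exactly one individual. Positions avoid
#' assembly-error sites so the truth categories stay disjoint.
#'
#' @param true_genome Result of [simulate_genome()].
#' @param config A [sim_config()] object.
#' @param truth Optional truth table from [inject_assembly_errors()]; used to
#'   keep allelic sites >= 50 bp away from error sites and to report allelic
#'   positions in assembly coordinates.
#' @return List with `individuals` (two lists: name, index, hap1, hap2) and
#'   truth data frames `between` and `within` (true and assembly
#'   coordinates).
#' @export
simulate_individuals <- function(true_genome, config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_dnastringset(if (is.list(true_genome)) true_genome$genome
                            else true_genome)
  repeats <- if (is.list(true_genome)) true_genome$repeats else NULL
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))

  with_seed(child_seed(config$seed, 3L), {
    avoid <- repeats
    tandem <- if (is.list(true_genome)) true_genome$tandem_sites else NULL
    if (!is.null(tandem) && nrow(tandem) > 0L)
      avoid <- rbind(avoid, data.frame(
        chrom = tandem$chrom, start = pmax(1L, tandem$start - 50L),
        end = tandem$start + 2L * tandem$size + 49L))
    if (!is.null(truth) && nrow(truth$edits) > 0L) {
      er <- data.frame(chrom = truth$edits$chrom,
                       start = pmax(1L, truth$edits$at_start - 50L),
                       end = truth$edits$at_end + 54L)
      avoid <- rbind(avoid, er)
    }
    m <- config$n_between_sites + config$n_within_sites
    sites <- sample_sites(m, chrom_lens, spacing = 50L, avoid = avoid,
                          end_margin = 200L)
    idx <- sample.int(m)
    bidx <- sort(idx[seq_len(config$n_between_sites)])
    widx <- sort(setdiff(seq_len(m), bidx))
    bases <- c("A", "C", "G", "T")
    refb <- vapply(seq_len(m), function(i)
      substr(as.character(genome[[sites$chrom[i]]]), sites$pos[i],
             sites$pos[i]), character(1))
    altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1L),
                   character(1), USE.NAMES = FALSE)

    between <- if (length(bidx)) {
      carrier <- sample(1:2, length(bidx), replace = TRUE)
      data.frame(chrom = sites$chrom[bidx], true_pos = sites$pos[bidx],
                 ref = refb[bidx],
                 allele_ind1 = ifelse(carrier == 1L, altb[bidx], refb[bidx]),
                 allele_ind2 = ifelse(carrier == 2L, altb[bidx], refb[bidx]))
    } else data.frame(chrom = character(0), true_pos = integer(0),
                      ref = character(0), allele_ind1 = character(0),
                      allele_ind2 = character(0))
    within <- if (length(widx)) {
      data.frame(chrom = sites$chrom[widx], true_pos = sites$pos[widx],
                 individual = sample(1:2, length(widx), replace = TRUE),
                 allele1 = altb[widx], allele2 = refb[widx])
    } else data.frame(chrom = character(0), true_pos = integer(0),
                      individual = integer(0), allele1 = character(0),
                      allele2 = character(0))

    if (!is.null(truth)) {
      between$assembly_pos <- lift_true_to_assembly(truth, between$chrom,
                                                    between$true_pos)
      within$assembly_pos <- lift_true_to_assembly(truth, within$chrom,
                                                   within$true_pos)
    } else {
      between$assembly_pos <- between$true_pos
      within$assembly_pos <- within$true_pos
    }

    mk_hap <- function(ind, hap) {
      g <- genome
      for (cn in names(g)) {
        b <- between[between$chrom == cn, , drop = FALSE]
        al <- if (ind == 1L) b$allele_ind1 else b$allele_ind2
        sub <- data.frame(pos = b$true_pos, val = al)
        w <- within[within$chrom == cn & within$individual == ind, ,
                    drop = FALSE]
        if (nrow(w) > 0L && hap == 1L)
          sub <- rbind(sub, data.frame(pos = w$true_pos, val = w$allele1))
        sub <- sub[sub$val != "", , drop = FALSE]
        # drop no-op replacements (allele equal to reference base)
        if (nrow(sub) > 0L) {
          g[[cn]] <- Biostrings::replaceAt(
            g[[cn]], IRanges::IRanges(sub$pos, sub$pos),
            as.character(sub$val))
        }
      }
      g
    }
    individuals <- lapply(1:2, function(i) {
      list(name = paste0("ind", i), index = i,
           hap1 = mk_hap(i, 1L), hap2 = mk_hap(i, 2L))
    })
    list(individuals = individuals, between = between, within = within)
  })
}

# --- short reads -------------------------------------------------------------

#' Simulate short re-sequencing reads from an individual
#'
#' Samples reads uniformly from both haplotypes, applies per-base
#' substitution errors, builds Phred quality strings (constant high quality
#' with geometric low-quality tails at the ends, enough to exercise the
#' trimming rule), and optionally appends 3' adapter sequence to a fraction
#' of reads (read-through / contamination).
#'
#' @param individual One element of `simulate_individuals()$individuals`.
#' @param config A [sim_config()] object.
#' @param read_length,paired Override the config library layout.
#' @param depth Override the per-individual target depth.
#' @param seed RNG seed; defaults to a child seed of `config$seed` keyed by
#'   the individual index.
#' @return A `short_reads` data frame (id, seq, qual, mate, pair) with a
#'   `truth` attribute recording each fragment's origin.
#' @export
simulate_short_reads <- function(individual, config,
                                 read_length = config$read_length,
                                 paired = config$paired,
                                 depth = config$depth,
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- child_seed(config$seed, 10L + individual$index)
  haps <- list(individual$hap1, individual$hap2)
  chrom_lens <- Biostrings::width(haps[[1]])
  names(chrom_lens) <- names(haps[[1]])
  G <- sum(chrom_lens)
  L <- as.integer(read_length)
  stopifnot(L <= min(chrom_lens))

  with_seed(seed, {
    if (paired) {
      n <- ceiling(depth * G / (2 * L))
      insert <- pmax(40L, pmin(as.integer(round(
        rnorm(n, config$insert_mean, config$insert_sd))), min(chrom_lens)))
    } else {
      n <- ceiling(depth * G / L)
      insert <- rep(L, n)
    }
    ci <- sample.int(length(chrom_lens), n, replace = TRUE, prob = chrom_lens)
    hap <- sample(1:2, n, replace = TRUE)
    start <- floor(runif(n, 1, chrom_lens[ci] - insert + 2)) |> as.integer()
    strand <- sample(c("+", "-"), n, replace = TRUE)

    frag <- character(n)
    for (h in 1:2) for (k in seq_along(chrom_lens)) {
      sel <- which(hap == h & ci == k)
      if (!length(sel)) next
      frag[sel] <- as.character(Biostrings::extractAt(
        haps[[h]][[k]], IRanges::IRanges(start[sel], width = insert[sel])))
    }

    ad1 <- config$adapters[1]
    ad2 <- if (length(config$adapters) > 1) config$adapters[2] else ad1
    fill <- function(genomic, adapter) {
      short <- nchar(genomic) < L
      out <- genomic
      if (any(short))
        out[short] <- paste0(genomic[short],
                             substr(adapter, 1L, L - nchar(genomic[short])))
      substr(out, 1L, L)
    }
    if (paired) {
      s1 <- fill(substr(frag, 1L, pmin(L, insert)), ad1)
      s2 <- fill(revcomp(substr(frag, pmax(1L, insert - L + 1L), insert)), ad2)
      swap <- strand == "-"
      tmp <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tmp
      seqs <- c(rbind(s1, s2))
      mate <- rep(c("mate1", "mate2"), n)
      pair <- rep(seq_len(n), each = 2L)
    } else {
      seqs <- substr(frag, 1L, L)
      neg <- strand == "-"
      seqs[neg] <- revcomp(seqs[neg])
      mate <- rep("single", n)
      pair <- rep(NA_integer_, n)
    }

    # adapter contamination: independent 3' run-in on a fraction of reads
    if (config$adapter_contam_rate > 0) {
      nn <- length(seqs)
      contam <- which(runif(nn) < config$adapter_contam_rate)
      if (length(contam)) {
        u <- sample(32:(L - 6L), length(contam), replace = TRUE)
        seqs[contam] <- paste0(substr(seqs[contam], 1L, u),
                               substr(ad1, 1L, L - u))
      }
    }

    if (config$error_rate > 0) seqs <- cpp_inject_errors(seqs, config$error_rate)
    quals <- make_quals(length(seqs), L, config$q_high, config$q_tail_frac,
                        config$q_tail_geom)

    ids <- if (paired) rep(sprintf("%s_r%07d", individual$name, seq_len(n)),
                           each = 2L)
           else sprintf("%s_r%07d", individual$name, seq_len(n))
    reads <- data.frame(id = ids, seq = seqs, qual = quals, mate = mate,
                        pair = pair)
    attr(reads, "truth") <- data.frame(
      id = sprintf("%s_r%07d", individual$name, seq_len(n)),
      chrom = names(chrom_lens)[ci], hap = hap, start = start,
      insert = insert, strand = strand)
    class(reads) <- c("short_reads", "data.frame")
    reads
  })
}

# Quality strings: constant q_high with geometric low-quality tails.
make_quals <- function(n, L, q_high, tail_frac, geom) {
  base <- strrep(intToUtf8(q_high + 33L), L)
  qs <- rep(base, n)
  for (end in c("5p", "3p")) {
    idx <- which(runif(n) < tail_frac)
    if (!length(idx)) next
    tl <- pmin(rgeom(length(idx), geom) + 1L, L - 2L)
    for (j in seq_along(idx)) {
      low <- intToUtf8(sample(2:15, tl[j], replace = TRUE) + 33L)
      if (end == "5p") substr(qs[idx[j]], 1L, tl[j]) <- low
      else substr(qs[idx[j]], L - tl[j] + 1L, L) <- low
    }
  }
  qs
}

# --- long reads --------------------------------------------------------------

#' Simulate long reads from an individual
#'
#' Read lengths follow a gamma distribution with mean
#' `config$long_read_mean` (default 377 bp); reads are sampled uniformly
#' from both haplotypes and carry per-base substitution errors.
#'
#' @inheritParams simulate_short_reads
#' @return A `long_reads` data frame (id, seq) with a `truth` attribute.
#' @export
simulate_long_reads <- function(individual, config,
                                depth = config$long_read_depth, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- child_seed(config$seed, 20L + individual$index)
  haps <- list(individual$hap1, individual$hap2)
  chrom_lens <- Biostrings::width(haps[[1]])
  names(chrom_lens) <- names(haps[[1]])
  G <- sum(chrom_lens)
  with_seed(seed, {
    n <- ceiling(depth * G / config$long_read_mean)
    len <- pmax(config$long_read_min, as.integer(round(
      rgamma(n, shape = config$long_read_shape,
             rate = config$long_read_shape / config$long_read_mean))))
    ci <- sample.int(length(chrom_lens), n, replace = TRUE, prob = chrom_lens)
    len <- pmin(len, chrom_lens[ci])
    hap <- sample(1:2, n, replace = TRUE)
    start <- floor(runif(n, 1, chrom_lens[ci] - len + 2)) |> as.integer()
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- character(n)
    for (h in 1:2) for (k in seq_along(chrom_lens)) {
      sel <- which(hap == h & ci == k)
      if (!length(sel)) next
      seqs[sel] <- as.character(Biostrings::extractAt(
        haps[[h]][[k]], IRanges::IRanges(start[sel], width = len[sel])))
    }
    neg <- strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    if (config$long_read_error > 0)
      seqs <- cpp_inject_errors(seqs, config$long_read_error)
    reads <- data.frame(id = sprintf("%s_L%07d", individual$name, seq_len(n)),
                        seq = seqs)
    attr(reads, "truth") <- data.frame(
      id = reads$id, chrom = names(chrom_lens)[ci], hap = hap, start = start,
      len = len, strand = strand)
    class(reads) <- c("long_reads", "data.frame")
    reads
  })
}

# --- optical map -------------------------------------------------------------

#' Simulate an optical restriction map
#'
#' Starts from the exact in-silico digest of each chromosome and applies the
#' measurement process of an optical mapping system: missed cuts (adjacent
#' fragments merge), spurious extra cuts (fragments split), per-fragment
#' multiplicative sizing noise (normal, sd = cv x length), and loss of
#' fragments below the minimum detectable size.
#'
#' @param genome Sequences to digest (DNAStringSet / named character / the
#'   result of [simulate_genome()]).
#' @param config A [sim_config()] object.
#' @param recognition,cut_offset Restriction site; defaults to SwaI
#'   (ATTTAAAT, blunt cut after base 4).
#' @param seed RNG seed; default derived from `config$seed`.
#' @return A list of `restriction_map` objects (source `"optical"`), one per
#'   chromosome.
#' @export
simulate_optical_map <- function(genome, config,
                                 recognition = "ATTTAAAT", cut_offset = 4L,
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- child_seed(config$seed, 30L)
  seqs <- as_chrom_character(genome)
  with_seed(seed, {
    lapply(names(seqs), function(cn) {
      dig <- digest_in_silico(seqs[[cn]], recognition, cut_offset,
                              map_id = cn)
      fr <- as.numeric(dig$fragments)
      # missed cuts: merge adjacent fragments
      if (length(fr) > 1L && config$missing_cut_prob > 0) {
        miss <- runif(length(fr) - 1L) < config$missing_cut_prob
        grp <- cumsum(c(1L, !miss))
        fr <- as.numeric(tapply(fr, grp, sum))
      }
      # extra cuts: split a fragment at a uniform position
      if (config$extra_cut_prob > 0 && length(fr) > 0L) {
        out <- list()
        for (f in fr) {
          if (f >= 2 && runif(1) < config$extra_cut_prob) {
            cut <- floor(runif(1, 1, f))
            out[[length(out) + 1L]] <- c(cut, f - cut)
          } else out[[length(out) + 1L]] <- f
        }
        fr <- unlist(out)
      }
      # sizing noise
      if (config$optical_cv > 0 && length(fr) > 0L)
        fr <- round(fr * rnorm(length(fr), 1, config$optical_cv))
      fr <- pmax(fr, 1)
      # desorption of small fragments
      if (config$min_fragment > 0) fr <- fr[fr >= config$min_fragment]
      restriction_map(fr, map_id = cn, source = "optical")
    })
  })
}

# --- whole study -------------------------------------------------------------

#' Simulate a complete re-sequencing study
#'
#' Runs the full generator: true genome with gene models, erroneous assembly
#' with truth table, two individuals (individual 1 sequenced single-end at
#' `se_read_length`, individual 2 paired-end at `read_length`, mirroring the
#' two-laboratory library structure), long reads from individual 1, and an
#' optical map of the true genome.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `config`, `genome`, `genes`, `repeats`,
#'   `assembly`, `truth`, `individuals`, `between`, `within`, `reads1`,
#'   `reads2`, `long_reads`, `optical`.
#' @export
simulate_study <- function(config) {
  g <- simulate_genome(config)
  inj <- inject_assembly_errors(g, config)
  ind <- simulate_individuals(g, config, truth = inj$truth)
  truth <- inj$truth
  truth$between_individual_sites <- ind$between
  truth$within_individual_sites <- ind$within
  reads1 <- simulate_short_reads(ind$individuals[[1]], config,
                                 read_length = config$se_read_length,
                                 paired = FALSE)
  reads2 <- simulate_short_reads(ind$individuals[[2]], config,
                                 read_length = config$read_length,
                                 paired = config$paired)
  lr <- simulate_long_reads(ind$individuals[[1]], config)
  om <- simulate_optical_map(g$genome, config)
  list(config = config, genome = g$genome, genes = g$genes,
       repeats = g$repeats, assembly = inj$assembly, truth = truth,
       individuals = ind$individuals, between = ind$between,
       within = ind$within, reads1 = reads1, reads2 = reads2,
       long_reads = lr, optical = om)
}
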