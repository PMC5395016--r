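# File-format interfaces: FASTA/FASTQ via Biostrings, plus small text
# writers/readers for GFF3, SAM, VCF, BED, truth tables and fragment lists.

#' Write sequences to FASTA
#'
#' @param x DNAStringSet, named character vector, or a `long_reads` data
#'   frame.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- stats::setNames(x$seq, x$id)
  Biostrings::writeXStringSet(as_dnastringset(x), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path Input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33)
#'
#' Mate suffixes `/1` and `/2` are appended to paired read names.
#'
#' @param reads A `short_reads` data frame (id, seq, qual, mate).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  suffix <- ifelse(reads$mate == "mate1", "/1",
                   ifelse(reads$mate == "mate2", "/2", ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, suffix, "\n", reads$seq, "\n+\n",
                    reads$qual), con)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a reads data frame
#' @param path Input file.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  stopifnot(length(x) %% 4 == 0)
  id <- sub("^@", "", x[seq(1, length(x), 4)])
  mate <- rep("single", length(id))
  mate[grepl("/1$", id)] <- "mate1"
  mate[grepl("/2$", id)] <- "mate2"
  base <- sub("/[12]$", "", id)
  pair <- ifelse(mate == "single", NA_integer_, match(base, unique(base)))
  reads <- data.frame(id = base, seq = x[seq(2, length(x), 4)],
                      qual = x[seq(4, length(x), 4)], mate = mate,
                      pair = pair)
  class(reads) <- c("short_reads", "data.frame")
  reads
}

#' Write gene models to GFF3
#' @param genes Feature data frame from [simulate_genome()].
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- ifelse(is.na(genes$parent), paste0("ID=", genes$id),
                  paste0("ID=", genes$id, ";Parent=", genes$parent))
  writeLines(paste(genes$chrom, "refgrade", genes$type, genes$start,
                   genes$end, ".", genes$strand,
                   ifelse(is.na(genes$phase), ".", genes$phase), attrs,
                   sep = "\t"), con)
  invisible(path)
}

#' Read gene models from GFF3
#' @param path Input file.
#' @export
read_gff3 <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "#") & nzchar(x)]
  f <- strsplit(x, "\t", fixed = TRUE)
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    ifelse(lengths(m) == 0 | m == "", NA_character_,
           sub(paste0(".*", key, "="), "", m))
  }
  a <- vapply(f, `[`, character(1), 9)
  data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    type = vapply(f, `[`, character(1), 3),
    start = as.integer(vapply(f, `[`, character(1), 4)),
    end = as.integer(vapply(f, `[`, character(1), 5)),
    strand = vapply(f, `[`, character(1), 7),
    phase = suppressWarnings(as.integer(vapply(f, `[`, character(1), 8))),
    id = vapply(a, get_attr, character(1), "ID", USE.NAMES = FALSE),
    parent = vapply(a, get_attr, character(1), "Parent", USE.NAMES = FALSE))
}

#' Write alignment records as SAM
#'
#' Minimal SAM text output (header plus the 11 mandatory fields) of the
#' internal mapper's records. SEQ is stored reference-oriented, as in SAM.
#'
#' @param records Alignment records from [map_reads()].
#' @param assembly The reference the records refer to.
#' @param path Output file.
#' @export
write_sam <- function(records, assembly, path) {
  seqs <- as_chrom_character(assembly)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs)), con)
  flag <- integer(nrow(records))
  paired <- records$mate %in% c("mate1", "mate2")
  flag <- flag + ifelse(paired, 1L, 0L)
  flag <- flag + ifelse(paired & records$mate == "mate1", 64L, 0L)
  flag <- flag + ifelse(paired & records$mate == "mate2", 128L, 0L)
  unmapped <- records$placement == "unmapped"
  flag <- flag + ifelse(unmapped, 4L, 0L)
  flag <- flag + ifelse(!unmapped & records$strand == "-", 16L, 0L)
  writeLines(paste(records$id, flag,
                   ifelse(unmapped, "*", records$chrom),
                   ifelse(unmapped, 0L, records$pos),
                   records$mapq,
                   ifelse(unmapped, "*", records$cigar),
                   "*", 0L, 0L,
                   records$seq_ref, "*",
                   paste0("NM:i:", ifelse(is.na(records$nm), 0L, records$nm)),
                   sep = "\t"), con)
  invisible(path)
}

#' Read alignment records from SAM
#'
#' Parses the minimal fields needed to rebuild pileups: name, flag, chrom,
#' pos, MAPQ, CIGAR, SEQ. Placement is `unique` for mapped records with
#' MAPQ > 0, `multiple` for mapped records with MAPQ 0 (as emitted by
#' [write_sam()]), `unmapped` otherwise.
#'
#' @param path Input file.
#' @export
read_sam <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "@")]
  f <- strsplit(x, "\t", fixed = TRUE)
  flag <- as.integer(vapply(f, `[`, character(1), 2))
  unmapped <- bitwAnd(flag, 4L) > 0L
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, "mate1",
                 ifelse(bitwAnd(flag, 128L) > 0L, "mate2", "single"))
  mapq <- as.integer(vapply(f, `[`, character(1), 5))
  data.frame(
    id = vapply(f, `[`, character(1), 1),
    chrom = ifelse(unmapped, NA_character_, vapply(f, `[`, character(1), 3)),
    pos = ifelse(unmapped, NA_integer_,
                 as.integer(vapply(f, `[`, character(1), 4))),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = mapq,
    cigar = ifelse(unmapped, NA_character_, vapply(f, `[`, character(1), 6)),
    seq_ref = vapply(f, `[`, character(1), 10),
    mate = mate,
    placement = ifelse(unmapped, "unmapped",
                       ifelse(mapq > 0L, "unique", "multiple")))
}

#' Write a truth table to tab-separated files
#' @param truth A `truth_table` from the simulator.
#' @param dir Output directory; writes `assembly_errors.tsv`,
#'   `between_individual_sites.tsv`, `within_individual_sites.tsv`.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("assembly_errors", "between_individual_sites",
               "within_individual_sites")) {
    df <- truth[[nm]]
    if (is.null(df)) next
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write restriction maps as a tab-separated fragment list
#'
#' One record per line: map id followed by the ordered fragment lengths.
#'
#' @param maps A `restriction_map` or list of them.
#' @param path Output file.
#' @export
write_fragments <- function(maps, path) {
  if (inherits(maps, "restriction_map")) maps <- list(maps)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in maps)
    writeLines(paste(c(m$map_id, m$fragments), collapse = "\t"), con)
  invisible(path)
}

#' Read restriction maps from a tab-separated fragment list
#' @param path Input file.
#' @param source Map source label (`"optical"` or `"in_silico"`).
#' @export
read_fragments <- function(path, source = "optical") {
  lapply(strsplit(readLines(path), "\t", fixed = TRUE), function(f) {
    restriction_map(as.numeric(f[-1]), map_id = f[1], source = source)
  })
}

#' Write site or indel calls as VCF
#'
#' Emits a minimal VCF 4.2 with INFO tags CLASS (combined class), CAT
#' (per-dataset R/N/A/L categories), DP (pooled depth) and, for indel
#' records, SVTYPE/SIZE.
#'
#' @param calls Data frame with chrom, pos, ref, alt, class and optionally
#'   cat1, cat2, catp, depth, type, size columns.
#' @param assembly Reference sequences (for the header).
#' @param path Output file.
#' @export
write_vcf <- function(calls, assembly, path) {
  seqs <- as_chrom_character(assembly)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", names(seqs), ",length=",
                      nchar(seqs), ">"),
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Combined site class\">",
               "##INFO=<ID=CAT,Number=3,Type=String,Description=\"Per-dataset R/N/A/L category (ds1,ds2,pooled)\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled depth\">",
               "##INFO=<ID=SIZE,Number=1,Type=Integer,Description=\"Indel size\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    info <- paste0("CLASS=", calls$class)
    if (!is.null(calls$cat1))
      info <- paste0(info, ";CAT=", calls$cat1, ",", calls$cat2, ",",
                     calls$catp)
    if (!is.null(calls$depth)) info <- paste0(info, ";DP=", calls$depth)
    if (!is.null(calls$size)) info <- paste0(
      info, ifelse(is.na(calls$size), "", paste0(";SIZE=", calls$size)))
    writeLines(paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                     "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Write intervals as BED
#' @param df Data frame with chrom, start, end (1-based closed) and
#'   optionally name.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  nm <- if (!is.null(df$name)) df$name else "."
  writeLines(paste(df$chrom, df$start - 1L, df$end, nm, sep = "\t"), path)
  invisible(path)
}

#' Write a whole simulated study to a directory
#'
#' Emits the simulator's artifacts in standard formats: true genome and
#' assembly FASTA, gene models GFF3, short-read FASTQ (per individual), long
#' read FASTA, optical fragment list, and the truth tables.
#'
#' @param sim Result of [simulate_study()].
#' @param outdir Output directory.
#' @export
write_study <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(outdir, "true_genome.fasta"))
  write_fasta(sim$assembly, file.path(outdir, "assembly.fasta"))
  write_gff3(sim$genes, file.path(outdir, "genes.gff3"))
  write_fastq(sim$reads1, file.path(outdir, "ind1.fastq"))
  write_fastq(sim$reads2, file.path(outdir, "ind2.fastq"))
  write_fasta(sim$long_reads, file.path(outdir, "long_reads.fasta"))
  write_fragments(sim$optical, file.path(outdir, "optical_map.tsv"))
  write_truth(sim$truth, file.path(outdir, "truth"))
  invisible(outdir)
}
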