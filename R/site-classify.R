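# Site classification: per-dataset R/N/A/L categories by base-frequency
# thresholds, combination of the two individuals and the pooled set into the
# five published genotype classes, 1-4 bp indel error calling, and per-10 kb
# rate arithmetic.

#' Classify pileup sites into R/N/A/L categories
#'
#' Applies the frequency rules per site: depth < `min_depth` reads is
#' "low depth" (L); >= 80% of reads identical to the reference base is
#' "reference type" (R); >= 80% of reads discordant with the reference base
#' is "non-reference type" (N, with the most frequent non-reference base
#' recorded as the call); two alleles each with >= 40% read support is
#' "allelic" (A). All thresholds are inclusive. Sites matching none of the
#' rules (e.g. 70/30) are the unresolved precursor "U" and are excluded from
#' the published classes downstream. Frequencies are computed over the full
#' depth including N bases. Rules are tested in the order L, R, N, A.
#'
#' @param pileup A `pileup` object.
#' @param min_depth Minimum depth for an assessable (effective) site.
#' @param ref_frac Reference/non-reference threshold (default 0.80).
#' @param allele_frac Allelic support threshold (default 0.40).
#' @return A `site_calls` list: per chromosome, a data frame with depth,
#'   ref_n, alt (dominant non-reference base), alt_n, second_n (support of
#'   the second most frequent allele overall) and cat (R/N/A/L/U), plus the
#'   raw count matrix rows A/C/G/T/N as columns nA..nN.
#' @export
classify_sites <- function(pileup, min_depth = 10, ref_frac = 0.8,
                           allele_frac = 0.4) {
  out <- lapply(names(pileup$counts), function(cn) {
    m <- pileup$counts[[cn]]
    L <- ncol(m)
    refc <- match(strsplit(pileup$ref[[cn]], "")[[1]],
                  c("A", "C", "G", "T"))
    refc[is.na(refc)] <- 5L
    depth <- colSums(m)
    ref_n <- m[cbind(refc, seq_len(L))]
    malt <- m
    malt[cbind(refc, seq_len(L))] <- -1L
    alt_i <- max.col(t(malt), ties.method = "first")
    alt_n <- m[cbind(alt_i, seq_len(L))]
    alt <- c("A", "C", "G", "T", "N")[alt_i]
    alt[alt_n <= 0L] <- NA_character_
    alt_n[alt_n < 0L] <- 0L
    nonref <- depth - ref_n
    top2 <- pmin(ref_n, alt_n)  # support of the weaker of the top-two alleles
    # NB with a biallelic site ref/alt are the top two; a site where two
    # non-reference alleles both exceed 40% cannot also have ref >= 40%
    # (sum > 1), and is caught by the N rule or left U.
    cat <- rep("U", L)
    cat[depth < min_depth] <- "L"
    eff <- depth >= min_depth
    cat[eff & ref_n >= ref_frac * depth] <- "R"
    cat[eff & cat == "U" & nonref >= ref_frac * depth] <- "N"
    cat[eff & cat == "U" & ref_n >= allele_frac * depth &
          alt_n >= allele_frac * depth] <- "A"
    df <- data.frame(depth = depth, ref_n = ref_n, alt = alt, alt_n = alt_n,
                     cat = cat)
    df$nA <- m[1, ]; df$nC <- m[2, ]; df$nG <- m[3, ]; df$nT <- m[4, ]
    df$nN <- m[5, ]
    df
  })
  names(out) <- names(pileup$counts)
  structure(list(sites = out, ref = pileup$ref,
                 params = list(min_depth = min_depth, ref_frac = ref_frac,
                               allele_frac = allele_frac)),
            class = "site_calls")
}

#' Classify a single pileup column
#'
#' Scalar convenience wrapper over the vectorised rules of
#' [classify_sites()], for a column given as base counts.
#'
#' @param counts Named counts (A/C/G/T/N, missing entries are 0).
#' @param ref_base Reference base at the column.
#' @param min_depth,ref_frac,allele_frac Thresholds as in
#'   [classify_sites()].
#' @return One of "R", "N", "A", "L", "U".
#' @export
classify_site <- function(counts, ref_base, min_depth = 10, ref_frac = 0.8,
                          allele_frac = 0.4) {
  full <- stats::setNames(rep(0L, 5L), c("A", "C", "G", "T", "N"))
  full[names(counts)] <- counts
  depth <- sum(full)
  if (depth < min_depth) return("L")
  ref_n <- full[[ref_base]]
  alt_n <- max(full[setdiff(names(full), ref_base)])
  if (ref_n >= ref_frac * depth) return("R")
  if ((depth - ref_n) >= ref_frac * depth) return("N")
  if (ref_n >= allele_frac * depth && alt_n >= allele_frac * depth) return("A")
  "U"
}

#' Combine per-dataset classifications into genotype classes
#'
#' Reconstructs the combination of the two individuals' categories and the
#' pooled set into the five published classes (reference, sequencing_error,
#' allele_within, allele_between, low_depth) plus unresolved. The exact
#' combination table of the source study is not published in its main text;
#' this is the package's documented reconstruction:
#'
#' \itemize{
#' \item pooled L: low_depth.
#' \item both individuals R: reference.
#' \item both N with the same recorded non-reference allele:
#'   sequencing_error; different alleles: unresolved.
#' \item one R, one N: allele_between (the individuals are homozygous for
#'   different alleles; no pooled confirmation is required because the
#'   pooled frequency of such a site is mechanically intermediate).
#' \item one individual polymorphic (category A, or minor-allele frequency
#'   >= `min_carrier_minor` with at least `min_carrier_count` minor reads),
#'   the other R, and the pooled category not N: allele_within with the
#'   carrier recorded. The relaxation below the strict 40% A rule
#'   compensates binomial sampling noise of a 50/50 het at the 10-read
#'   minimum depth (a true het falls below 40% minor frequency ~26% of the
#'   time at 20x) while the 4-read floor keeps the same-base-error false
#'   positive probability ~1e-8 per site; motivated in the package vignette,
#'   both knobs exposed.
#' \item both individuals A with the same allele: allele_within, carrier
#'   "both".
#' \item an individual (or both) L but the pooled set assessable: defer to
#'   the pooled category -- R: reference; N: sequencing_error flagged
#'   low-confidence; A: allele_within with carrier undetermined;
#'   U: unresolved.
#' \item anything else: unresolved, excluded from published-class counts.
#' }
#'
#' @param calls1,calls2,callsp `site_calls` for individual 1, individual 2
#'   and the pooled dataset (built over the same assembly).
#' @param min_carrier_minor Carrier minor-allele frequency floor
#'   (default 0.20 = allele_frac/2).
#' @param min_carrier_count Carrier minor-allele read-count floor
#'   (default 4).
#' @return A `combined_calls` list of per-chromosome data frames with
#'   columns class, carrier, alt, low_confidence.
#' @export
combine_datasets <- function(calls1, calls2, callsp,
                             min_carrier_minor = 0.20,
                             min_carrier_count = 4L) {
  chroms <- names(calls1$sites)
  stopifnot(identical(chroms, names(calls2$sites)),
            identical(chroms, names(callsp$sites)))
  out <- lapply(chroms, function(cn) {
    s1 <- calls1$sites[[cn]]; s2 <- calls2$sites[[cn]]; sp <- callsp$sites[[cn]]
    if (any(sp$depth < pmax(s1$depth, s2$depth)))
      stop("inconsistent inputs: pooled depth below an individual depth at ",
           "some sites of ", cn)
    n <- nrow(s1)
    class <- rep("unresolved", n)
    carrier <- rep(NA_character_, n)
    alt <- rep(NA_character_, n)
    lowconf <- rep(FALSE, n)

    c1 <- s1$cat; c2 <- s2$cat; cp <- sp$cat
    same_alt <- !is.na(s1$alt) & !is.na(s2$alt) & s1$alt == s2$alt

    # pooled low depth
    sel <- cp == "L"
    class[sel] <- "low_depth"

    both <- cp != "L" & c1 != "L" & c2 != "L"

    # reference
    sel <- both & c1 == "R" & c2 == "R"
    class[sel] <- "reference"

    # sequencing error: both non-reference with the same allele
    sel <- both & c1 == "N" & c2 == "N" & same_alt
    class[sel] <- "sequencing_error"
    alt[sel] <- s1$alt[sel]

    # allele between individuals: one R, one N
    sel <- both & ((c1 == "R" & c2 == "N") | (c1 == "N" & c2 == "R"))
    class[sel] <- "allele_between"
    alt[sel] <- ifelse(c1[sel] == "N", s1$alt[sel], s2$alt[sel])

    # allele within an individual: polymorphic carrier (A or a relaxed-U
    # meeting the minimum-evidence floors), the other individual R, pooled
    # not N (an N pooled set would indicate an error, not a het)
    minor_n1 <- pmin(s1$ref_n, s1$alt_n)
    minor_n2 <- pmin(s2$ref_n, s2$alt_n)
    poly1 <- both & !is.na(s1$alt) &
      (c1 == "A" | (c1 == "U" & minor_n1 >= min_carrier_minor * s1$depth &
                      minor_n1 >= min_carrier_count))
    poly2 <- both & !is.na(s2$alt) &
      (c2 == "A" | (c2 == "U" & minor_n2 >= min_carrier_minor * s2$depth &
                      minor_n2 >= min_carrier_count))
    sel <- class == "unresolved" & poly1 & c2 == "R" & cp != "N"
    class[sel] <- "allele_within"; carrier[sel] <- "ind1"; alt[sel] <- s1$alt[sel]
    sel <- class == "unresolved" & poly2 & c1 == "R" & cp != "N"
    class[sel] <- "allele_within"; carrier[sel] <- "ind2"; alt[sel] <- s2$alt[sel]
    sel <- class == "unresolved" & both & c1 == "A" & c2 == "A" & same_alt
    class[sel] <- "allele_within"; carrier[sel] <- "both"; alt[sel] <- s1$alt[sel]

    # an individual (or both) low depth but pooled assessable: defer to pooled
    onel <- cp != "L" & (c1 == "L" | c2 == "L")
    sel <- onel & cp == "R"
    class[sel] <- "reference"
    sel <- onel & cp == "N"
    class[sel] <- "sequencing_error"; alt[sel] <- sp$alt[sel]
    lowconf[sel] <- TRUE
    sel <- onel & cp == "A"
    class[sel] <- "allele_within"; carrier[sel] <- "undetermined"
    alt[sel] <- sp$alt[sel]

    data.frame(class = class, carrier = carrier, alt = alt,
               low_confidence = lowconf)
  })
  names(out) <- chroms
  structure(list(combined = out), class = "combined_calls")
}

#' Call 1-4 bp indel errors and allelic indels
#'
#' Runs anchored indel alleles through the same frequency thresholds as
#' substitution sites, treating the indel as the non-reference allele at its
#' anchor column: support >= `ref_frac` of the anchor depth calls an error
#' record; support and plain-allele each >= `allele_frac` calls an allelic
#' indel. Only lengths 1-4 are emitted. Calls are made on the pooled pileup.
#' Following the package-wide correction-action convention, a read-insertion
#' allele (assembly lacks bases) yields an `insertion` error record and a
#' read-deletion allele a `deletion` record.
#'
#' When alignment records are supplied, the frequency denominator is refined
#' by a per-read replay: only reads whose alignment spans the event window
#' (5 bp of flank beyond the anchored event on both sides) are counted, and
#' support is recounted within that informative set. This removes the bias
#' of the raw anchor-column depth, which includes boundary reads physically
#' unable to report the full event (for a 4 bp insertion in 70 bp reads,
#' roughly a fifth of the spanning reads).
#'
#' @param pileup The pooled `pileup`.
#' @param min_depth,ref_frac,allele_frac Thresholds as in
#'   [classify_sites()].
#' @param max_len Maximum emitted indel length (default 4).
#' @param records Optional alignment records underlying `pileup` (the pooled
#'   union) for the replay denominator.
#' @return List with `errors` (chrom, position = anchor, type, ref_allele,
#'   corrected_allele, size, support, depth) and `allelic` (same columns).
#' @export
call_small_indels <- function(pileup, min_depth = 10, ref_frac = 0.8,
                              allele_frac = 0.4, max_len = 4,
                              records = NULL) {
  idx <- pileup$indels
  empty <- data.frame(chrom = character(0), position = integer(0),
                      type = character(0), ref_allele = character(0),
                      corrected_allele = character(0), size = integer(0),
                      support = integer(0), depth = integer(0))
  if (nrow(idx) == 0L) return(list(errors = empty, allelic = empty))
  idx <- idx[idx$len >= 1L & idx$len <= max_len, , drop = FALSE]
  if (nrow(idx) == 0L) return(list(errors = empty, allelic = empty))
  dep <- pileup_depth(pileup)
  idx$depth <- mapply(function(cn, a) dep[[cn]][a], idx$chrom, idx$anchor)
  idx <- idx[idx$depth >= min_depth, , drop = FALSE]
  if (nrow(idx) == 0L) return(list(errors = empty, allelic = empty))
  if (!is.null(records)) {
    # pre-filter to plausible candidates, then replay exact denominators
    cand <- idx$count >= pmax(3L, floor(0.25 * idx$depth))
    idx <- idx[cand, , drop = FALSE]
    if (nrow(idx) == 0L) return(list(errors = empty, allelic = empty))
    for (i in seq_len(nrow(idx))) {
      rp <- replay_indel_site(records, pileup$ref, idx$chrom[i],
                              idx$anchor[i], idx$type[i], idx$len[i],
                              idx$seq[i])
      idx$count[i] <- rp["support"]
      idx$depth[i] <- rp["informative"]
    }
    idx <- idx[idx$depth >= min_depth, , drop = FALSE]
    if (nrow(idx) == 0L) return(list(errors = empty, allelic = empty))
  }
  f <- idx$count / idx$depth
  plain <- (idx$depth - idx$count) / idx$depth
  rec <- function(sel) {
    if (!any(sel)) return(empty)
    s <- idx[sel, , drop = FALSE]
    data.frame(chrom = s$chrom, position = s$anchor,
               type = ifelse(s$type == "ins", "insertion", "deletion"),
               ref_allele = ifelse(s$type == "ins", "-", s$seq),
               corrected_allele = ifelse(s$type == "ins", s$seq, "-"),
               size = s$len, support = s$count, depth = s$depth)
  }
  list(errors = rec(f >= ref_frac),
       allelic = rec(f >= allele_frac & plain >= allele_frac & f < ref_frac))
}

# Replay one candidate indel site over the alignment records: informative =
# reads whose alignment spans [anchor - 5, anchor + size + 5] on the
# reference (5 bp of flank is roughly the gap open+extend cost in match
# points, the minimum anchoring needed for the aligner to place a gap
# reliably); support = informative reads carrying a same-type event whose
# left-normalised anchor matches. Sequence/length agreement is not required:
# a sequencing error inside the inserted bases still supports the event,
# just as the non-reference category at a substitution site sums all
# discordant bases.
replay_indel_site <- function(records, ref, chrom, anchor, type, size, seq) {
  lo <- anchor - 5L
  hi <- anchor + size + 5L
  # cheap span pre-filter: pos <= lo and pos + read span + 8 >= hi
  sel <- which(records$chrom == chrom & !is.na(records$pos) &
                 records$pos <= lo &
                 (records$pos + nchar(records$seq_ref) + 8L) >= hi)
  informative <- 0L
  support <- 0L
  for (i in sel) {
    ops <- parse_cigar(records$cigar[i])
    ref_len <- sum(ops$len[ops$op %in% c("M", "D", "=", "X")])
    if (records$pos[i] + ref_len - 1L < hi) next
    informative <- informative + 1L
    hit <- FALSE
    # walk ops, normalise any indel at/near the anchor
    rp <- records$pos[i]
    qp <- 1L
    s <- records$seq_ref[i]
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) { rp <- rp + len; qp <- qp + len }
      else if (op == "I") {
        nn <- normalize_indel(ref[[chrom]], rp - 1L,
                              "ins", substr(s, qp, qp + len - 1L))
        if (type == "ins" && nn$anchor == anchor) hit <- TRUE
        qp <- qp + len
      } else if (op == "D") {
        nn <- normalize_indel(ref[[chrom]], rp - 1L, "del",
                              substr(ref[[chrom]], rp, rp + len - 1L))
        if (type == "del" && nn$anchor == anchor) hit <- TRUE
        rp <- rp + len
      } else if (op == "S") qp <- qp + len
      else if (op == "N") rp <- rp + len
    }
    if (hit) support <- support + 1L
  }
  c(support = support, informative = informative)
}

# Parse a CIGAR string into op/length vectors.
parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = substring(m, nchar(m)),
             len = as.integer(substring(m, 1L, nchar(m) - 1L)))
}

#' Rate per 10,000 nucleotides
#'
#' `count / effective_sites * 10000`, reported at 2 decimals (4 decimals for
#' rates below 0.01), the precision used for published error/allele rates.
#'
#' @param count Number of sites of the class.
#' @param effective_sites Number of assessable (depth >= 10) sites.
#' @return The rounded rate.
#' @export
compute_rate <- function(count, effective_sites) {
  stopifnot(effective_sites > 0)
  r <- count / effective_sites * 1e4
  ifelse(r < 0.01, round(r, 4), round(r, 2))
}

#' Extract substitution error records from combined calls
#'
#' Sites classified `sequencing_error` become snp-type error records with the
#' assembly base as `ref_allele` and the reads' consensus as
#' `corrected_allele`.
#'
#' @param combined A `combined_calls` object.
#' @param site_calls The pooled `site_calls` (for reference bases).
#' @return Error-record data frame (chrom, position, type = "snp",
#'   ref_allele, corrected_allele, size = 1).
#' @export
snp_error_records <- function(combined, site_calls) {
  rows <- lapply(names(combined$combined), function(cn) {
    cc <- combined$combined[[cn]]
    sel <- which(cc$class == "sequencing_error" & !is.na(cc$alt) &
                   cc$alt != "N")
    if (!length(sel)) return(NULL)
    refb <- substring(site_calls$ref[[cn]], sel, sel)
    data.frame(chrom = cn, position = sel, type = "snp", ref_allele = refb,
               corrected_allele = cc$alt[sel], size = 1L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), position = integer(0),
                      type = character(0), ref_allele = character(0),
                      corrected_allele = character(0), size = integer(0))
  out
}

#' Extract allelic SNP sites from combined calls
#'
#' @param combined A `combined_calls` object.
#' @param site_calls The pooled `site_calls`.
#' @param classes Which classes to extract (default the two allele classes).
#' @return Data frame chrom, pos, ref, alt, class, carrier.
#' @export
allelic_sites <- function(combined, site_calls,
                          classes = c("allele_within", "allele_between")) {
  rows <- lapply(names(combined$combined), function(cn) {
    cc <- combined$combined[[cn]]
    sel <- which(cc$class %in% classes & !is.na(cc$alt))
    if (!length(sel)) return(NULL)
    data.frame(chrom = cn, pos = sel,
               ref = substring(site_calls$ref[[cn]], sel, sel),
               alt = cc$alt[sel], class = cc$class[sel],
               carrier = cc$carrier[sel])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), carrier = character(0))
  out
}
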