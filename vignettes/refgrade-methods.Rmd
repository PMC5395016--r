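---
title: "Grading a reference assembly with re-sequencing reads and an optical map: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{refgrade methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refgrade)
```

# The problem

A finished, clone-by-clone reference assembly is the yardstick against
which every re-sequenced individual of the species is measured, so its
residual defects matter disproportionately. `refgrade` implements three
complementary validation channels:

1. **Deep short-read re-sequencing of two individuals** exposes single-base
   and 1–4 bp indel errors: at a true error, *every* read from *both*
   individuals disagrees with the assembly. Crucially, two individuals
   allow errors to be separated from allelic variation — sites where the
   individuals are homozygous for *different* bases (independently
   propagated laboratory populations accumulate mutations), and sites
   heterozygous within one individual (residual heterozygosity or somatic
   mutation), are biology, not error.
2. **Long reads** (mean 377 bp) expose large (≥ 100 bp) indel-scale
   misassemblies through split local alignments.
3. **An optical restriction map** provides an assembly-independent scaffold
   check: the in-silico SwaI digest of each pseudomolecule must reproduce
   the ordered fragment lengths measured on genomic DNA molecules, and the
   unmatched optical fragments at a physical gap estimate its true size.

Every stage is driven by a seeded synthetic-data generator with a recorded
truth table, so the pipeline's operating characteristics are measurable.

# Site classification model

Per dataset (individual 1, individual 2, pooled union of their retained
alignments) and per site with read depth ≥ `min_depth` (default 10, below
which a site is **L**, unassessable):

* **R** — reads matching the reference base ≥ 80 % of depth;
* **N** — reads discordant with the reference base ≥ 80 % of depth
  (summed over alternative bases; the most frequent one is recorded as the
  call);
* **A** — two alleles each supported by ≥ 40 % of depth;
* otherwise the site is an unresolved precursor (**U**) — e.g. a 70/30
  site — which the published rules genuinely leave undefined.

All thresholds are inclusive (≥), frequencies are computed over the full
depth including N bases, and the rules are tested in the order L, R, N, A
(a site satisfying both N and A — only possible with two alternative
alleles — is called N; at realistic error rates this is vanishingly rare).

The pooled dataset is re-piled from the union of both individuals'
alignments, not an average of categories; its depth is the sum of the
individual depths.

## Combining the three classifications

The published description names the five output classes but not the exact
combination table, so the table below is this package's documented
reconstruction:

| ind 1 | ind 2 | pooled | class |
|---|---|---|---|
| R | R | — | reference |
| N | N (same allele) | — | sequencing_error |
| N | N (different allele) | — | unresolved |
| R | N (either order) | — | allele_between |
| polymorphic | R | not N | allele_within (carrier recorded) |
| A | A (same allele) | — | allele_within (carrier "both") |
| L (either or both) | | R / N / A / U | reference / sequencing_error (low-confidence) / allele_within (carrier undetermined) / unresolved |
| L | L | L | low_depth |
| anything else | | | unresolved |

"Polymorphic" is category A **or** a U-site whose minor allele reaches
≥ `min_carrier_minor` (default 0.20 = half the A threshold) with at least
`min_carrier_count` (default 4) supporting reads. This relaxation is
deliberate and quantitative: a true 50/50 heterozygote sampled at 20×
shows both alleles at ≥ 40 % only ~74 % of the time
(`sum(dbinom(8:12, 20, 0.5))`), so the strict A rule alone cannot reach
high within-allele sensitivity at realistic depths. The two floors bound
the false-positive risk instead: four identical error reads at a
same-base error rate of ~0.17 % per read have probability ~1e-8 per site.
The pooled set is only required *not* to be N (an N pooled set indicates an
error, not a het); it is not required to be A, because a one-individual het
dilutes to ~25 % in the pooled set and would fail a 40 % rule almost
always. The between-individual rule (R + N) likewise needs no pooled
confirmation: the pooled frequency of such a site is mechanically
intermediate (~50 %) and often lands in A or U depending on sampling.

An `allele_between` call means the two re-sequenced individuals are
homozygous for different bases; a site where both are N for *different*
non-reference alleles is left unresolved (conflicting evidence about what
the true base is).

## Small indels

Anchored, left-normalised indel alleles from the gapped alignments go
through the same thresholds, treating the indel as the non-reference allele
at its anchor column: support ≥ 80 % calls an error record, support and
plain allele both ≥ 40 % an allelic indel; only lengths 1–4 are emitted,
and calls are made on the pooled pileup (the published result is a single
genome-wide indel count, not a per-dataset combination).

The frequency denominator matters more for indels than for SNPs. The raw
anchor-column depth includes boundary reads that physically cannot report
the event — a read must span the whole event plus enough flank for the
aligner to open a gap — which depresses the apparent support of 3–4 bp
events by roughly 20 % in 70 bp reads. When alignment records are
available, `call_small_indels()` therefore replays candidate sites
per read: the denominator counts only reads spanning
`[anchor − 5, anchor + size + 5]` (5 bp ≈ the gap open + extend cost in
match points, the minimum anchoring needed to place a gap reliably), and a
read supports the event if it carries a same-type indel normalising to the
same anchor, regardless of the exact inserted/deleted sequence — an error
*inside* the inserted bases still supports the event, just as the N
category sums all discordant bases at a substitution site.

## Error/variant orientation

Throughout the package, indel naming follows the correction action on the
assembly (the convention of the split-read channel): an **insertion** error
means the assembly *lacks* bases (reads show an insertion; correction
inserts and lengthens the assembly), a **deletion** error means the
assembly carries *extra* bases (correction deletes). Truth tables, pileup
alleles, error records and split-read events all share this orientation, so
`apply_corrections()` arithmetic is uniform: new length = old length +
Σ insertion sizes − Σ deletion sizes.

# The read-processing plumbing

Trimming removes bases < Q20 from both ends until two or more consecutive
bases ≥ Q20 are seen; the kept span may retain internal low-quality bases.
Adapter clipping truncates before the leftmost 3'-anchored adapter
occurrence with ≥ 5 bp overlap and ≤ 10 % mismatches (the published
protocol names the clipping tool but not its settings; these are exposed,
documented defaults). Reads < 32 bp are discarded and broken pairs
relabelled "unpaired".

The built-in mapper is a desk-scale stand-in for a production short-read
aligner: k-mer seeds (k = 21) at three read offsets on both strands,
candidates deduplicated within ±6 bp, perfect candidates accepted
ungapped, all others resolved by a full affine-gap DP
(match +1, mismatch −2, gap open −3, extend −1) over a padded window.
Accepting "few-mismatch" ungapped candidates without the DP is a trap worth
recording: around an indel in locally periodic sequence, a shifted ungapped
alignment can fake 2–3 mismatches and silently erase the indel signal. A
read is `unique` only when its best score beats every other candidate by
≥ 6 (two mismatches' worth); exact repeat copies tie and become `multiple`,
excluded downstream. Mapping confidence is 60/0 — only the ≥ 20 cutoff
semantics matter. Reads failing `score ≥ length − 16` are unmapped, which
also rejects reads overhanging large-event breakpoints by > ~5 bp.

Coordinates are 1-based closed throughout (the R/Bioconductor convention),
including all emitted reports.

# Split-read large indels

Local hits come from k-mer seeding (k = 15), diagonal clustering and
greedy X-drop extension; a hit is ambiguous if another hit covers ≥ 50 % of
the same read interval within 6 score points. Reads > 50 % simple-tandem
(periods ≤ 8) are skipped — the desk-scale stand-in for repeat-library
masking. Two unambiguous same-chromosome, same-strand hits, consistently
ordered, within 1 Mbp, jointly covering > 90 % of the read, yield an event
of size `read_gap − ref_gap`.

A consequence of the > 90 % coverage rule deserves emphasis: a large
insertion of *novel* sequence is undetectable at ~377 bp read lengths,
because the unaligned novel bases are part of the read (a 200 bp novel
insertion caps coverage at ~47 %). The detectable insertion geometry is a
lost **tandem duplication** — the individuals carry S·S where the assembly
has a single S — whose split hits overlap on the reference (negative
reference gap) and cover the read completely. The synthetic generator
therefore plants tandem loci for its large-insertion errors; real erroneous
indels of this kind are likewise reported adjacent to tandem repeats.
Deletion-type events (assembly carries extra sequence) have no such
constraint.

Corroboration (≥ 2 reads with breakpoints within 10 bp, plus an optional
short-read coverage-collapse signal over the extra segment) replaces the
manual inspection a production pipeline would apply to split-read
candidates; both knobs are exposed.

# Optical-map model

The in-silico digest cuts after base 4 of each non-overlapping ATTTAAAT
occurrence (SwaI's standard site; N runs never match) and conserves total
length exactly. The fragment-map aligner is a dynamic program over blocks
pairing runs of up to `max_merge` = 3 fragments per side, scored as

score(block) = 3 − z²/2 − 4·(extra fragments merged),  z = (Σo − Σi)/sd,

with sd = cv · max(Σi, 2 kb) and skip penalties 2 (optical), 3 (in-silico)
or 1 for fragments below the 1.2 kb detection limit (desorption). The merge
penalty 4 ≈ −ln(0.02) is the log-likelihood of one missed/extra cut at the
simulated 2 % cut-error rate; an earlier ad-hoc value of 1 let ≥ 5 kb
foreign fragments be absorbed into merged blocks beside large fragments
instead of being reported. Ties break deterministically (score, then fewer
merged fragments, then leftmost); the DP is verified against exhaustive
enumeration on all small instances.

Discordant elements — unmatched runs, blocks ≥ 5 kb off, and cut-site
disagreements — are grouped within 100 kb and classified: gap overlap →
class 1; ≥ 2 cut disagreements with ≥ 2 unmatched fragments and > 10 %
total-size disagreement → class 5; ≥ 2 cut disagreements → class 4;
unmatched run ≥ 5 kb → class 2; block difference ≥ 5 kb → class 3;
sub-5 kb class-2/3 events are suppressed. A *cut-site disagreement* is a
block merged on **both** sides (≥ 2:2, crossed sizes): a 1:k block is
exactly the expected signature of a single missed or extra cut, i.e.
measurement noise, and raising it as a discordance would bury real events
under noise regions. The class-4/5 thresholds are explicit stand-ins — the
published classification is qualitative. Gap size is the sum of unmatched
optical fragments anchored at the gap, flagged unsupported when zero.

# The synthetic world

The generator's defaults are the stated test-bed: a 1 Mb, 2-chromosome
genome at 44 % GC (rice-like); 10 % exact-repeat content in 200–2000 bp
dispersed units (real repeats are diverged and partially mappable; exact
copies make "uniquely mappable" unambiguous at desk scale, so a modest
fraction replaces the genome-wide 39 % of the real plant); 40 gene models
with UTR/CDS/intron structure on both strands (ATG-initiated, internally
stop-free CDS); 100 substitution + 25/25 small-indel assembly errors
(≥ 50 bp apart, non-repeat); one 200 bp tandem-loss insertion and one
500 bp extra-segment deletion (≥ 10 kb apart, outside genes); 20
between-individual and 20 within-individual allelic sites; two individuals
sequenced at 20× each — individual 1 single-end 51 bp, individual 2
paired-end 76 bp at 150 ± 15 bp inserts — with 0.5 % per-base error,
constant Q38 with geometric low-quality tails (15 % of read ends) and 2 %
3'-adapter run-in; long reads gamma-distributed with mean 377 bp at 5×;
and an optical map with 5 % sizing CV, 2 % missed/extra-cut rates and a
1.2 kb detection limit. Seeds are mandatory; every generator is
deterministic under its seed, with stage-specific child seeds.

What a green test does **not** establish: instrument-realistic error
profiles (errors are uniform substitutions, uncorrelated with the quality
tails), diverged repeat families, diploid recombination, GC-coverage bias,
chimeric reads, or the behaviour of the thresholds at the published data's
scale and depth profile (7.9× / 35.7×). Those would all lower the measured
sensitivities.

## Recovery metric

`evaluate_recovery()` reports sensitivity over *effective* truth sites —
pooled depth ≥ 10, and for the allele classes per-individual depth ≥ 10 —
mirroring the pipeline's own assessability rule: a site without the
required depth is declared low-depth by construction, not missed.
Unconditional counts are also reported (`n_truth` vs `n_effective`).
Precision is over all calls of the class.

# Numerical and reporting choices

* Rates per 10,000 nucleotides print at 2 decimals, 4 when below 0.01;
  genome sizes in Mbp at 1 decimal; percentages at 1 decimal.
* Effect severity for site-level summaries: Nonsense > Missense > Silent >
  UTR > Intron > Intergenic (the published six-way scheme is unranked;
  per-transcript detail is retained). Start-loss and stop-loss fold into
  Missense, splice-region changes into Intron.
* Physical-gap placeholders are 1,000 Ns; telomeric N runs use the same
  length (no published value).
* Indels are left-normalised (anchor shifts left while the preceding base
  equals the last event base), both in pileups and in truth records, so
  calls and truth compare by exact position.
* Proper-pair insert bounds default to mean ± 4 sd of the first 10,000
  observed spans.
* Degenerate inputs: empty sequences digest to empty maps; empty read sets
  and empty call tables produce empty (not failing) reports; overlapping
  correction records are rejected with the offending positions listed.

# Known limitations

* The mapper and local aligner are desk-scale: genome sizes in the tens of
  megabases are the practical ceiling, and mapping qualities are binary
  (60/0), not calibrated probabilities.
* The five-class combination table is a reconstruction; the published
  original is not in the main text of the source study.
* Large *novel* insertions (not tandem-derived) are undetectable by the
  split-read channel's own selection rules at 377 bp read lengths — a
  property of the rules, not of this implementation.
* Class-4/5 optical discordance boundaries are explicit stand-ins for a
  qualitative published description.
* `allele_within` carriers at the depth floor (10–13 reads) are missed when
  fewer than 4 minor-allele reads are sampled (~5 % of hets at depth 13);
  this is the stated trade-off against same-base-error false positives.
* When one individual falls below the depth floor, the combination defers
  to the pooled category and cannot tell a within-allele from a
  between-allele: a pooled-A site is reported `allele_within` with carrier
  "undetermined", even if the hidden individual was homozygous for the
  alternative. The low-confidence flag marks the analogous deferred
  sequencing-error calls.
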