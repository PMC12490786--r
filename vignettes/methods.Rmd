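---
title: "Quantifying adenine base-editing outcomes from amplicon sequencing"
author: "abequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adenine base-editing outcomes from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abequant)
```

## Scope and model

`abequant` analyses the sequencing readouts of an adenine base-editing (ABE)
experiment at a single amplicon locus, here the *HBB* Makassar-surrogate
protospacer `TTCTCCTCAGGAGTCAGATG`. Three readouts are covered:

1. **Amplicon deep sequencing** of the edited locus: paired-end reads are
   merged, quality-filtered, anchored at the PCR primers, globally aligned to
   the wild-type amplicon, and grouped into wild-type reads, reads carrying
   A-to-G edits at the tracked adenines (A9 on-target surrogate; A12, A16,
   A18 bystanders), reads with other substitutions, and indel-bearing reads.
2. **Sanger traces of clonal colonies**, consumed as per-position base
   proportion tables, from which each colony is genotyped as unedited,
   monoallelic or biallelic at A9.
3. **Multiplexed amplicon panels** (rhAMPseq-style) over hundreds of
   candidate off-target sites sampled longitudinally, with a statistical
   caller that contrasts post-treatment allele frequencies against a
   pre-treatment background error model.

A synthetic-data generator produces all three kinds of input with known
ground truth, so every stage is testable without animal sequencing data.

## Read processing

Merging scans every overlap length from the configured minimum (10 bp) to
the full read length and keeps the overlap with the most matching bases,
subject to a maximum mismatch fraction of 0.25; ties go to the longer
overlap. In the overlap the higher-Phred base wins and the consensus quality
is the maximum of the pair. The merged read is then quality-filtered — it
fails when strictly more than 2 bases fall below the low-quality threshold —
and finally anchored: the forward primer must match the 5' end and the
reverse-complemented reverse primer the 3' end, each within 2 substitutions
and with no indels, in either read orientation. Reads matching in both
orientations indicate a malformed amplicon and are rejected.

Two of these constants are conventions of this package rather than
measurements: the numeric meaning of "low quality" (Phred < 20, the
conventional Q20 cutoff) and the order of operations
(merge → quality filter → anchor). Both are exposed as arguments so their
sensitivity can be examined.

## Alignment and read classification

Anchored reads are aligned to the inter-primer reference with an affine-gap
global aligner at EMBOSS-needle default scoring: match 5, mismatch −4, gap
opening 10 (charged on the first gap base), gap extension 0.5 per additional
base; `N` scores 0 against anything, and end gaps are penalized like
internal gaps. Ties are broken deterministically (substitution over gap,
then gap-in-query over gap-in-reference). The implementation is validated in
the test suite against two independent routes: a plain-R dynamic-programming
oracle — exhaustively over all sequence pairs of lengths ≤ 2, across random
pairs of lengths 3–8, and on 100 random length-50 pairs — and the
`Biostrings` pairwise aligner under the equivalent gap parameterisation.
The exhaustive tier stops at length 2 and is supplemented by random longer
pairs because the pair count grows as `4^(2L)`; the chosen sizes keep the
check under a minute while still covering every gap/mismatch topology the
scorer distinguishes.

A read is classified `INDEL` when any alignment gap overlaps the protospacer
extended by a 10-bp flank — the flank (configurable) covers lesions at the
protospacer boundary while keeping distant artefacts out; otherwise `EDIT`
with the set of named adenines showing A-to-G; otherwise `WT` when no
substitution falls inside the protospacer, else `SUBST_OTHER`. Two
precedence decisions are deliberate: an A9 edit accompanied by an incidental
substitution elsewhere still counts as `EDIT` (the substitution remains
visible in the positional table), and indel reads are excluded from the
per-position frequency table, because gapped columns have no well-defined
base identity; indel frequencies are instead computed over **all** retained
reads, so the two summaries use consistent denominators of their own.

Duplication calling deserves a note: an insertion is reported as a
duplication when the inserted sequence equals the immediately adjacent
reference k-mer — or the adjacent k-mer of the read itself. The second
clause matters because a tandem duplication that arises on an edited allele
copies the edit into both repeats, so neither matches the wild-type k-mer
even though the molecule is unambiguously a duplication.

Frequencies are kept as fractions internally and printed as percentages in
reports. Protospacer positions are 1-based, 5'→3' on the protospacer
strand, so all summaries are strand-invariant: defining the locus on the
minus strand and feeding reverse-complemented reads reproduces identical
tables (this is a regression test).

## Colony genotyping

The edited-signal fraction at a tracked adenine is `G / (A + G)` of the
trace proportions at that position; when less than half the signal is A or
G the estimate is indeterminate (likely a mixed or indel trace). Diploid
genotype bands are symmetric around the expectations 0, 0.5 and 1: below
0.2 unedited, 0.2–0.8 monoallelic, above 0.8 biallelic. The thresholds are
package conventions (the underlying trace-analysis literature does not fix
them) and are arguments. A trace is flagged as indel-bearing when ≥ 5
consecutive positions at or after the protospacer start have a maximum base
proportion below 0.7 — the trace-desynchronisation signature of a
heterozygous indel. Size decomposition of such indels is out of scope; the
flag is the surrogate.

## Off-target discovery and the panel caller

Candidate sites are enumerated by an exact mismatch scan (no bulges) of
every 20-mer window on both strands, keeping windows within 4 mismatches of
the spacer whose 3'-adjacent 3-mer matches an IUPAC PAM pattern (`NNN` by
default, reflecting the PAM promiscuity of the NRCH Cas9 variant). `N` in
the reference counts as a mismatch. Sites are ranked by the published MIT
(Hsu) specificity score; its 20-entry weight vector is an external published
constant embedded as `hsuWeights()`. Panel selection keeps all sites below
the maximum mismatch tier and fills the remainder with the best-scoring
maximum-tier sites, ties broken by coordinate — the tie-break is this
package's convention. Genome-scale searches are out of scope; the enumerator
is exercised on synthetic contigs where a brute-force scan is feasible as an
oracle.

The panel caller works per subject on one pre-treatment and several
post-treatment samples:

* **Depth filter**: a site is analysed only with strictly more than 1000
  reads; failures are treated as missing data, never as zero frequency.
* **SNP rule**: a substitution above 10% pre-treatment that is present
  (≥ 10%, configurable) at every depth-passing later timepoint is a
  germline SNP and is excluded from background and calling.
* **Background**: mean and sample (n−1) SD of per-position base error rates
  (1 − reference-base frequency) pooled across all protospacer positions of
  all retained sites, SNP positions excluded.
* **Candidates**: a position must exceed both `mean + 2·SD` and an absolute
  0.5% floor in at least one post-treatment sample. The two thresholds are
  interpreted as a conjunction: the floor encodes the practical detection
  limit while the 2-SD rule anchors calling to measured noise.
* **Test**: a one-sample, one-sided t-test of the post-treatment frequencies
  against the subject's pre-treatment frequency at the same position
  (alternative *greater* — editing can only add the alternative allele);
  all 20 protospacer positions are assessed. Degenerate inputs follow fixed
  conventions: all post values equal to pre gives t = 0, p = 0.5; zero
  variance away from the pre value gives the limiting p of 0 or 1; fewer
  than two usable post observations yields an indeterminate call. A pooled
  mode (`pooled = TRUE`) exists for pooling frequencies across subjects but
  is off by default, and no multiple-testing correction is applied, matching
  standard practice for this assay.

Nearest-gene annotation of significant calls is a plain interval query over
BED/GFF features (distance 0 when overlapping; exonic/intronic from feature
types; lexicographic tie-break, flagged).

## The synthetic-data generator

The generator encodes the statistical structure the analysis assumes, at
the study's operating points:

* allele fractions: A9 edit 0.6 by default (the ex vivo editing regime);
  A12 linked to A9 through `P(A12) = P(A9)·cond + (1 − P(A9))·marginal`
  with `cond = 0.08` and `marginal = 0`, so A12 appears essentially only on
  A9-edited alleles at a few percent overall; A16/A18 at 5×10⁻⁴, below the
  reliable detection limit; cytosine deamination at C5, C6, C8 around
  10⁻³ split predominantly C>T and C>G, with C3 left silent;
* indels as whole-allele events (a clone carries the indel): by default a
  duplication of 8 bp at 10⁻³ and of 7 bp at 5×10⁻⁴ inside the
  protospacer;
* sequencing noise: independent per-base substitution errors at 10⁻³ per
  sequenced base — a typical Illumina substitution rate, chosen here as a
  convention since no error magnitude is implied by the assay itself — kept
  **silent in quality** (errored bases still claim Phred 37), plus an
  independent low-quality process (Phred 2 at 10⁻³) that exists purely to
  exercise the quality filter. Separating the two processes lets tests
  distinguish "filterable" from "invisible" noise;
* reads as overlapping 2×150 bp pairs (R1 forward, R2 reverse-complement)
  over a 250-bp amplicon, so the merger is always exercised; a flag emits
  pre-merged reads.

The panel generator draws exact multinomial counts per position from an
error + SNP + edit mixture; pre-treatment samples carry SNPs and error but
no edits, and edits switch on at a configurable post-treatment onset.

What the generator does **not** model: PCR duplicates and chimeras, index
hopping, quality-score drift along the read, strand bias, and real genomic
repeat structure around off-target sites. Passing tests therefore
demonstrate the correctness of the statistical machinery under the stated
generative assumptions, not robustness to every artefact of real libraries.

## Problem sizes and determinism

The shipped tests and the acceptance script use 10⁴ read pairs for rate
recovery, 10⁵ for rare-indel recovery, 300 colonies, and 200 simulated
panels of 50 sites × 16 samples for the caller's type-I error and power —
sizes at which three-binomial-SD checks are sharp while a full run stays in
the minutes range on one core. All simulators are seeded and byte-identical
under a fixed seed; the pipelines themselves draw no random numbers, so
outputs are reproducible end to end (also a regression test).

## Known limitations

* The aligner is exact but quadratic; it is intended for amplicon-length
  sequences, not genome-scale alignment.
* The EditR-style normalisation of trace signal and its significance model
  are not reproduced; the plain-proportion estimator is a deliberate
  simplification and behaves accordingly on noisy traces.
* The SNP rule requires a pre-treatment sample; subjects without one cannot
  be analysed (this is inherent to the background-contrast design).
* Off-target enumeration has no bulge (gapped) mode and no CFD score.
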