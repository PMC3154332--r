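---
title: "Mining polymorphic microsatellites from multi-individual assemblies"
author: "microsatMiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining polymorphic microsatellites from multi-individual assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsatMiner)
```

## The problem

Developing microsatellite (SSR/STR) markers traditionally means designing
many primer pairs and genotyping them wet-lab, only to discard the loci
that amplify monomorphic products — a costly failure mode in species
with low genetic diversity. When a transcriptome (or any assembly) has
been sequenced from *pooled individuals*, the aligned reads at a repeat
locus carry population information before any PCR is run: if reads show
two or more distinct repeat-length variants, the locus is probably
polymorphic. microsatMiner automates that idea end to end:

1. **Scan** contigs for perfect di-/tri-/tetranucleotide repeats of at
   least five units (`scanFasta()`).
2. **Profile** each locus from read-to-contig alignments: count motif
   units per spanning read, build the allele histogram, classify
   variability (`profileLoci()`), and screen primer sites for SNPs
   (`screenPrimerSites()`).
3. **Select** candidates by flanking sequence, coverage, annotation,
   genome mapping and isogroup redundancy (`selectCandidates()`).
4. **Validate** in silico calls against observed PCR outcomes:
   heterozygosities, Hardy–Weinberg tests, null-allele frequencies,
   Fisher exact concordance, category summaries, and backward-deletion
   GLMs (`concordance()`, `fitPolymorphismGlms()`, ...).
5. **Simulate** pooled-individual read data with controlled error
   processes so every stage is testable without external data
   (`simulateReads()`).

## Repeat detection model

A locus is a *maximal perfect tract*: `unitCount` complete copies of a
2–4 bp motif, not extendable by a full copy on either side. Partial
trailing copies are excluded from both the unit count and the reported
coordinates, so `end - start + 1 == motifSize * unitCount`. Three
normalization rules keep reporting unambiguous:

* **Canonical motif** — the lexicographically minimal rotation
  (`canonicalizeMotif("TTG")` is `"GTT"`), so one tract is never
  reported under two rotations.
* **Smallest period** — a tract expressible at period *p* and *2p* is
  reported only at *p* (`"ATATATATATAT"` is six units of `AT`, never
  three units of `ATAT`). Motifs that are repetitions of a shorter
  string are rejected as periodic.
* **Stranded reporting** — reverse complements are *not* collapsed:
  transcript consensus sequences have a defined orientation, so `AC`
  and `GT` loci are distinct. (Whether the original SSR search tools
  also scan the reverse strand is tool-specific; we scan the given
  strand only, which is the conservative choice for stranded cDNA.)

Anything outside A/C/G/T terminates a tract, and input is uppercased.
Internally loci live in a `GRanges` (1-based inclusive, the Bioconductor
convention); the TSV interchange format is likewise 1-based inclusive,
while BED exports are 0-based half-open per the BED specification.
Compound or interrupted repeats, e.g. `(AC)5TT(AC)4`, are two separate
loci (each judged against the unit threshold on its own).

The scanner is verified against a brute-force oracle that extends every
(start, period) pair by per-position comparison; the two agree exactly
on thousands of random sequences.

## Read-level allele profiling

The in silico "genotype" of a locus is read-level, not individual-level:
pooled reads cannot be assigned to individuals, so an *in silico allele*
is a distinct repeat-unit count among reads, and the *consensus
genotype* is the modal count.

`countUnits()` classifies one aligned read against one locus:

* **non_spanning** — the aligned span does not cover the tract plus an
  `anchorLen` (default 5 bp) flank on both sides. Unit counts from
  partial tracts would be lower bounds, not alleles, so such reads are
  excluded; the anchor rule is our explicit, reproducible version of
  the "read must span the repeat" judgement a human makes in an
  assembly viewer.
* **irregular** — the flank anchors do not exactly match the contig, or
  the extracted tract segment (bases aligned between the anchors,
  insertions inside the tract included, deletions shrinking it) is not
  a whole number of perfect motif copies. A substitution inside the
  tract therefore cannot fabricate a length allele — it disqualifies
  the read instead. Irregular reads are tallied but never enter the
  histogram.
* **counted** — the tract segment is `k` perfect copies; the read
  contributes to histogram class `k` (`k = 0` is legal: the whole tract
  may be deleted in the read).

`buildProfile()` aggregates counted reads: histogram, number of distinct
length classes (`nAlleles`), consensus (modal) unit count with ties
broken towards the contig-consensus count and then towards the smaller
count (a fixed, documented rule; the choice is arbitrary but must be
deterministic), off-consensus read count, and the smallest observed unit
count (`min_units`, the length proxy used as a GLM predictor). A locus
is **variable** when some non-consensus class holds at least
`minMinorReads` reads. The default is 1, which reproduces a
classification in which even one discordant read marks a locus variable;
since single discordant reads may be sequencing (slippage) errors rather
than rare alleles — the central confound of the approach — the same knob
set to 2 or 3 implements the stricter "several discordant reads" policy
recommended when choosing loci to carry forward.

`screenPrimerSites()` protects against null alleles: per-column base
counts over designated primer-site windows (SAM deletions and assembly
pads never count towards depth), reporting SNP columns where at least
two bases reach `snpMinMinorReads` (default 2) reads, with minor allele
frequency and the region's minimum depth. A primer-site SNP, or
coverage too low to exclude one, flags the locus as at risk of
non-amplifying alleles.

## Candidate selection

`selectionRules()` quantifies the classic marker-selection criteria:
minimum flank per side (default 30 bp — enough for a primer plus slack;
the criterion is qualitative in the field, so the threshold is exposed
as a parameter), minimum read depth over tract + flanks (default 2),
required annotation and genome mapping, optional required variability,
and one representative per isogroup (the most allele-rich locus, ties
by depth then locus id). Every locus is annotated with the full list of
rules it fails, never just a pass/fail bit, so relaxing thresholds is
an auditable operation. Note that the per-locus filters are monotone
(relaxing a threshold can only add loci) but isogroup deduplication is
not: a newly admitted locus can displace a previously selected
representative of the same isogroup.

## Validation statistics

* `heterozygosities()` — observed heterozygosity and Nei's unbiased
  expected heterozygosity `(2n/(2n-1)) (1 - sum p_i^2)`; the correction
  makes the estimator unbiased for the population gene diversity
  `1 - sum p_i^2`.
* `chakrabortyNull()` — null-allele frequency
  `r = (He - Ho)/(He + Ho)`; negative values are expected noise when
  the true frequency is near zero and samples are small.
* `hweExact()` — conditional on allele counts: full enumeration of the
  genotype-array distribution for biallelic loci, seeded Monte-Carlo
  permutation of the allele vector otherwise; two-sided P is the
  probability of arrays at most as likely as the observed one. Returns
  `NA` when the minor allele has fewer than two copies (a single
  heterozygote carrying the only minor copy makes the test degenerate).
* `fisherExact2x2()` — full hypergeometric enumeration; the two-sided
  P sums point probabilities not exceeding the observed one (relative
  tolerance 1e-7), the convention of mainstream statistical software.
  `stats::fisher.test()` serves as an independent cross-check in the
  test suite, never as the implementation.
* `fitPolymorphismGlms()` — backward deletion: repeatedly drop the term
  whose removal costs the least deviance unless the loss is significant
  under a likelihood-ratio chi-square at `alpha` (default 0.05,
  least-significant-first — the conventional reading of "standard
  deletion testing", which does not prescribe tie rules). Complete
  separation is detected and flagged rather than silently reported.
* `hochbergCorrect()` — step-up family-wise correction via
  `stats::p.adjust`.

The packaged transcriptions of the published validation tables
(`table1Fixture()`, 21 scoreable loci; `table2Fixture()`, the 2x2
concordance counts) let the package reproduce the printed summary
numbers exactly; the per-individual genotypes behind them were never
published, so the heterozygosity/HWE columns of that table are consumed
as data, not recomputed, and the GLM coefficients of the original
analysis (which require unpublished per-locus data) are out of scope.

```{r concordance}
tab <- table2Fixture()
tab
fisherExact2x2(tab)
```

## The read simulator

`simulationConfig()` describes the study the generator emulates; its
defaults are the design constants of the motivating study — 12 pooled
individuals, mean depth 19.4x, mean read length 286 bp, 854 bp contigs
(the mean isotig length) — plus error-process values the original study
does not state, chosen once at field-realistic levels: substitution
rate 0.001/base and slippage rate 0.01 per read-tract, the right order
of magnitude for pyrosequencing-era data where homopolymer/repeat
errors dominate. Each contig carries one locus (candidate loci are
handled per-transcript); when no explicit per-locus allele spectrum is
given, half the loci are polymorphic with 2–4 alleles at Dirichlet-like
frequencies — there is no published census of the true polymorphic
fraction, and one half gives balanced classes for exercising the
concordance machinery.

Slippage is modelled as whole-unit gain/loss of one motif copy in a
read's tract, matching the definition of an in silico allele, so the
configured slippage rate is exactly the expected off-consensus read
fraction at a monomorphic locus — the error-versus-rare-allele confound
as a tunable property. Partial-unit damage arises via substitutions and
surfaces as irregular reads. Reads are single-end, forward-strand,
uniform-start, with constant placeholder qualities; CIGARs encode
non-consensus tract lengths as whole-motif insertions/deletions placed
at the tract (soft clips where read tract bases cannot be placed
against the consensus). Individual labels exist only in the truth
tables, never in the SAM — exactly the information loss of pooled
sequencing.

What the simulator deliberately does **not** emulate: flowgram-level
noise, quality-score realism, coverage biases, paired ends, chimeric
reads, and assembly errors in the consensus itself. Tests passing on
simulated data therefore certify the *logic* (counting, classification,
statistics) under a clean error model, not performance on real 454
data, where irregular-read rates will be higher and anchors may need
lengthening.

`makeLocusRecords()` closes the loop: it joins truth and profiles with
a stochastic wet-lab model (amplification probability, default 0.76 —
the conversion fraction observed in the motivating study — and
polymorphism probabilities conditional on truth) into the locus-record
schema the validation statistics consume.

## Numerical and design choices

* All Monte-Carlo operations take explicit seeds and restore the
  caller's RNG state; identical seeds give byte-identical FASTA, SAM
  and TSV outputs.
* Writers are atomic (temp file + rename); every TSV carries a comment
  header recording the tool version and parameters.
* Modal ties, isogroup ties and selection ordering are all resolved by
  fixed documented rules so the pipeline is order-independent.
* Problem sizes used in the shipped checks (chosen to make Monte-Carlo
  error small relative to the tolerances, while keeping the suite quick
  on one CPU): scanner-vs-oracle on 2–5 kb sequences over a dozen
  seeds; 500 depth-20 loci for two-allele recovery; 10,000 reads for
  the slippage-rate property; 100,000 permutations for the Monte-Carlo
  vs enumeration HWE comparison; 200 replicates of n = 200 for the
  GLM deletion-testing study.

## Limitations

Mono-, penta- and hexanucleotide repeats are out of scope, as are
imperfect-repeat scoring, phasing reads to individuals, base-quality
aware genotype likelihoods, primer design itself (windows are exported
for an external tool) and annotation generation (a precomputed table is
consumed). In silico allele counts from pooled reads are biased towards
common alleles — fewer discovery individuals than genotyping
individuals means rare alleles can be missed — so in silico variability
is a proxy, not a genotype.
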