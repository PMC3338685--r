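---
title: "Methods: assembly evaluation and tag-based DGE in TagSeqTools"
author: "TagSeqTools maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly evaluation and tag-based DGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TagSeqTools)
```

# The setting

Before reference genomes were common, transcriptomes of non-model
organisms were built by de novo assembly of short paired-end RNA-Seq
reads, and expression across tissues was measured with restriction-site
tags: NlaIII cuts cDNA at its palindromic CATG site, MmeI releases the 17
bases downstream, and the resulting 21 bp tag is sequenced in millions of
copies per library. Each analytical step of that design — evaluating
competing assemblies, characterizing the assembled sequences, turning raw
tags into per-transcript expression, and calling differential expression
between tissue libraries — involves small, well-defined computations that
are easy to get subtly wrong. TagSeqTools implements them as one tested
toolkit, with a synthetic-data generator that reproduces the statistical
structure of such an experiment so that every step can be verified
against planted ground truth.

# Assembly evaluation: union-coverage sensitivity and accuracy

Given a *gold standard* (known full-length coding sequences) aligned
against an assembly, high-scoring segment pairs (HSPs) are filtered on
length (≥ 50 bp), identity (≥ 90 %) and E-value (< 1e-10; the built-in
ungapped finder reports no E-value, so that criterion passes vacuously
for it and bites only on ingested external alignments). Aligned intervals
are merged per sequence so that overlapping regions count once; writing
TP for the merged (union) aligned length,

* sensitivity `Sen = TP / (TP + FN)` is computed on gold-standard
  coordinates over **all** gold sequences (FN = unaligned reference
  bases), and
* accuracy `Acc = TP / (TP + FP)` on assembly coordinates over the
  assembly sequences having **at least one** qualifying HSP
  (FP = their unaligned bases).

Two design points were genuinely open and are settled as follows. First,
TP is measured separately on each side: reference-side and assembly-side
union lengths coincide only for gap-free one-to-one alignments, and using
one number for both would leave one denominator ill-defined. Second,
`Acc` counts only assembly sequences with a surviving HSP; counting the
whole transcriptome would drive accuracy toward zero whenever the gold
set is far smaller than the assembly, which contradicts how the metric is
used to rank assemblies. When no HSP survives, `Sen` is 0 and `Acc` is
reported as `NA` with a warning rather than an arbitrary number.

The built-in HSP finder is deliberately minimal: exact 11-mer seeding on
both strands, ungapped extension at +1/−2 with an X-drop of 20. It is
meant for synthetic and small real data; production-scale searches should
be run externally and ingested via `readBlastTabular()` (12-column
tabular format, 1-based inclusive coordinates, minus-strand subject hits
normalized on read).

# Sequence characterization

**ORFs.** Only complete ORFs are counted: ATG through an in-frame stop,
no internal stop, stop included in the length, in all six frames. ORFs
truncated by sequence ends are excluded — counting partial ORFs would
make the length-class table depend on contig fragmentation rather than on
gene content. Per transcript the longest ORF is the representative (ties:
lowest forward-strand start, then '+' before '−').

**Codon usage and GC.** The terminal stop codon is excluded from codon
usage and GC accounting (the CodonW convention) but tallied in its own
stop-codon distribution. GC1/GC2/GC3 are G+C proportions at the three
codon positions of counted codons. Amino-acid property classes are
non-polar {G,A,V,L,I,P,F,M,W}, polar-uncharged {S,T,C,Y,N,Q}, acidic
{D,E}, basic {K,R,H}; other partitions exist in the literature, so
published class percentages computed under an unknown partition may not
be exactly recoverable — the class map here is stated so results are
unambiguous.

**SSRs.** A microsatellite is a maximal perfect tandem repeat of a
primitive 2–6 nt motif whose whole-copy total length reaches 18 bp — so
dinucleotides need 9 copies, trinucleotides 6, tetranucleotides 5,
pentanucleotides 4, hexanucleotides 3. The threshold is expressed as a
total length, not per-motif copy minima, because that is how such surveys
state it; a consequence worth noting is that tetra- and pentanucleotide
repeats must still reach 18 bp with whole repeats (20 bp in practice).
Overlapping candidate calls (a long repeat is periodic under several
anchorings) are resolved to the longest, then the smaller motif, then the
leftmost. Two SSRs at most 100 bp apart are flagged compound, the MISA
convention. Motifs are grouped into canonical strand- and
rotation-invariant classes (`AG/CT`, `AAG/CTT`, `AT/AT`, …): the class
representative is the lexicographic minimum over the motif's rotations
and its reverse complement's rotations.

# The tag pipeline

Every CATG site with at least 17 downstream bases yields a catalog tag on
the sense strand; sites at least 17 bases from the 5' end also yield the
antisense tag (assembled transcripts have arbitrary orientation, so
mapping must consider both). The *representative* tag — the one an
oriented mRNA actually produces — is the 3'-most sense-strand tag.
Transcripts with no CATG site can never be observed in tag data and are
reported as untaggable; this is a real phenomenon, not an edge case, and
the generator plants a small fraction of such transcripts.

Clean-tag filtering drops tags containing ambiguity codes, tags matching
configured adapter prefixes (none by default: the adapters of any given
protocol should be supplied explicitly), and tags whose library-wide copy
number is 1 — the standard treatment of sequencing-noise singletons. Each
rule is switchable and reported separately.

Mapping allows at most one mismatch over the 21 positions, with exact
hits pre-empting 1-mismatch hits to limit spurious ambiguity. A tag is
*unambiguous* when it maps to exactly one transcript, even at several
positions within it. Transcript counts sum unambiguous tag counts;
ambiguous tags still count as mapped in the ledger but contribute to no
transcript. TPM divides by the library's clean-tag total and scales by
1e6, so tag-level TPM sums to one million per library by construction.
The full ledger (raw, clean, distinct, mapped, unambiguous, tag-mapped
transcripts, unknown) satisfies the identities
`unknown = clean − mapped` and
`distinctUnknown = distinctClean − mappedDistinct` exactly; percentages
are rendered half-up to two decimals, and the averages column takes
arithmetic means over libraries (integers for counts).

# Differential and specific expression

The differential test is the two-sided conditional exact test: given a
transcript's counts `a`, `b` in two libraries with effective sizes
`N_A`, `N_B`, the null distribution of `a` conditional on `a + b` is
hypergeometric, and the two-sided p-value sums the probabilities of all
tables no more probable than the observed one. This is implemented
directly from `dhyper` enumeration (the support is only `0 … a+b`), and
the test suite cross-checks it against an independent implementation of
the same conditional test. DETs require p ≤ 0.05 and |log2FC| ≥ 1 on raw
p-values — multiple-testing correction is reserved for term enrichment,
where Bonferroni over the tested terms is applied. SETs use raw counts
with a strict rule: zero in one library, more than 11 tags in the other.

Two defaults deserve explanation. The *effective library size* defaults
to the mapped clean-tag total (the tags that can possibly contribute to
any transcript), switchable to the clean total; no formula for it is
canonical in the tag-DGE literature. The log2 fold change is computed on
counts normalized by the effective sizes with a pseudo-count of 0.5 tags
substituted for zeros — for display and thresholding only; significance
always comes from the exact test, which handles zeros exactly.

Pooled group comparisons (e.g. leaves = {YL, ML} vs roots = {FR, ITR,
ETR, HTR}) sum counts and effective sizes over members, treating member
libraries as replicates of a pooled sample; with singleton groups this
reduces exactly to the pairwise comparison.

# The synthetic-data generator

The generator emulates the study design the pipeline assumes:

* **Transcripts.** `nTranscripts` (default 500) i.i.d. sequences,
  lengths uniform on 400–2000 bp, background GC 0.44 (typical of dicot
  coding regions); half carry a planted complete ORF of 300 nt whose
  codons are drawn base-wise at the GC target with stop codons rejected;
  SSRs are planted per specification with periodicity-breaking flanks so
  the planted copy number is exact; 2 % of transcripts are stripped of
  CATG sites (untaggable), and all others are guaranteed a usable site.
* **Reads.** 75 bp paired ends; insert sizes are integer-rounded draws
  from Normal(200, 11) truncated to what the source transcript can host
  — sd 11 bp makes ~93 % of inserts fall within ±10 % of 200 bp, the
  figure such libraries typically report. Per-cycle Phred quality decays
  linearly (0.35 per cycle, capped at 40) so the median crosses Q30
  exactly at cycle 61 forward / 56 reverse, and substitution errors are
  injected at the per-cycle Phred-implied rate.
* **Tag libraries.** Per transcript, one Gamma(1/φ, ·) draw of true
  abundance shared across libraries, then Poisson counts per library:
  marginally the counts are negative binomial with mean 50 and
  dispersion φ = 0.2 (typical tag-count overdispersion), while *null*
  transcripts remain exchangeable between libraries — this is what makes
  the conditional exact test valid on null data, and it is the honest
  interpretation of "same expression, noisy counts". A fresh NB draw per
  library would instead encode true biological variation in every
  transcript and no exact test would hold its level. A configurable
  fraction (default 10 %) of transcripts is silenced in designated
  libraries (default YL) to create specifically expressed transcripts;
  optional planted effects multiply the Poisson mean in chosen libraries.
  Noise tags — random CATG+17-mers, 98 % singletons, 2 % doubletons —
  make up 5 % of the tag mass by default, emulating the unknown-tag
  fraction of real libraries. No published noise model exists for such
  libraries; these defaults are conventions and are only asserted
  against themselves.

One integer seed governs everything; each stage reseeds from the seed
plus a fixed offset, so stages are reproducible individually and jointly.

What the generator does *not* emulate: allelic variation in polyploids,
viral or contaminant sequence, assembler behaviour (the pipeline's
pseudo-assembly for evaluation is a deterministic degradation of the
truth), adapter chemistry, or position-specific error profiles beyond the
linear quality decay. Tests passing on synthetic data therefore certify
the arithmetic and the statistical calibration of the methods, not their
robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* Coordinates are 1-based and closed throughout, the Bioconductor
  convention; external 12-column alignments arrive 1-based inclusive and
  need no shift, and minus-strand subject coordinates are normalized on
  read.
* Percentage rendering is round-half-up to two decimals (`floor(x·100 +
  0.5)/100`), matching how published tag ledgers are printed; base R's
  banker's rounding would differ on exact halves.
* The exact test compares table probabilities with a relative tolerance
  of 1e-7 when summing the two-sided tail, the standard guard against
  floating-point ties.
* `N` never matches in the HSP finder or the read mapper, and counts as
  non-GC; tags containing `N` are removed by the ambiguity rule.
* Empty inputs are contracts, not crashes: zero read pairs yield a valid
  empty FASTQ pair, zero proper pairs an empty insert summary with a
  warning, zero surviving HSPs `Sen = 0` with `Acc = NA`, an empty
  sequence set a length-statistics error.

# Problem sizes

The default test-and-demonstration sizes — hundreds of transcripts,
thousands of read pairs, 10,000 null transcripts for calibration, 1,000
random instances for the interval-union oracle — were chosen as the
smallest sizes at which the Monte Carlo assertions (±0.005 on a
proportion at n = 1e5 inserts; 3 standard errors on the type-I rate at
n = 1e4) are sharp enough to catch real defects; the whole suite runs in
a couple of minutes on one CPU. All scale linearly if larger runs are
wanted.

# Session info

```{r}
sessionInfo()
```
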