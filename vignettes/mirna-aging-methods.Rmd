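---
title: "Methods: miRNA target anticorrelation, small-RNA annotation, and sponge design"
author: "miraging authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA target anticorrelation, small-RNA annotation, and sponge design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miraging)
```

# Scope and model

`miraging` implements the computational core of a common study design in
aging transcriptomics: a microRNA (the motivating case is the miR-29
family in the short-lived killifish brain) rises strongly with age, and
one asks (i) whether its predicted targets are anticorrelated with it
across an age series, (ii) whether those targets are overrepresented in
clusters of age-regulated genes, (iii) how gene expression responds when
the miRNA is antagonized with a sponge (decoy) transgene, and (iv) how
that response compares, gene by gene, with normal aging. Around this
sit two sequence-level tools — a mismatch-tolerant small RNA-seq
annotator for quantifying mature miRNAs, and a seed-site scanner with
site mutagenesis and sponge construct design — plus a seeded synthetic
data generator that emulates the study's data structure so every stage
can be validated end to end.

# The synthetic-data generator

`sim_config()` holds the study conditions. Defaults encode the design
the analysis assumes and are fixed once:

* **Ages** 5, 12, 20, 27, 39 weeks — sexual maturity through
  exceptional survivors — with **5 replicates per age** (25 samples).
* **miRNA trajectory**: geometric interpolation of the mean from
  `base_mirna` (50 RPKM-like units) to 15× that value
  (`mirna_fold_change = 15`), matching the observed >15-fold rise of
  the dominant miR-29 primary transcript. A geometric (log-linear)
  path was chosen because the observed rise is monotone and expression
  effects compose multiplicatively; with `noise_sigma = 0` the
  oldest/youngest mean ratio is exactly the configured fold change,
  which downstream tests exploit.
* **Coupling**: each of `n_targets = 200` target genes (out of
  `n_genes = 1000`) is repressed by `coupling = 1` log2 unit per
  standard deviation of the standardized log2 miRNA level; non-targets
  are independent of the miRNA.
* **Noise**: multiplicative log-normal with `noise_sigma = 0.3`
  (natural-log scale). The log-normal keeps RPKM-like values positive
  and is the conventional first-order model for biological spread in
  bulk expression; no mean-correction term is applied, since all
  downstream statistics are location/correlation based.
* **Reads**: 1000 fixed-length 50-nt reads, each a mature sequence with
  a 3' isomiR length offset drawn from `isomir_len_shift` (default mass
  0.55 at 0, with offsets −2 … +4; positive offsets add random
  untemplated bases), followed by the 3' adapter
  `TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC`, truncated to the read length,
  with per-base substitution (0.001) and N (0.001) rates.
* **DEG tables**: fold-change magnitudes are |N(1, 0.25)| floored at
  0.1 so direction is never ambiguous; every emitted row passes
  FDR < 0.05.

A single seeded generator is threaded through each simulation function
in a documented draw order (miRNA noise, baselines, target sampling,
noise matrix; for reads: sources, shifts, extensions, errors, Ns), so
identical configurations give byte-identical outputs, and the caller's
RNG state is saved and restored.

What the generator does *not* emulate: count-based sampling noise
(values are continuous, not negative-binomial counts), correlated gene
modules, batch effects, ligation bias in small-RNA libraries, and
templated (genome-encoded) isomiR extensions. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not robustness to every artifact of real libraries.

# Small-RNA preprocessing and two-phase annotation

Preprocessing follows the standard small RNA-seq recipe: drop reads
containing `N`; trim the 3' adapter; keep reads of 18–33 nt.

**Adapter trimming.** A read suffix is trimmed when it aligns to a
prefix of the adapter. The mismatch budget is prorated with overlap
length *L*: `min(2, floor(L/8))`, and overlaps shorter than 6 nt are
never trimmed — a full-length overlap tolerates the conventional two
mismatches while 1–2-nt chance matches cannot cause spurious trims. The
left-to-right scan (earliest acceptable start = longest trim) is
iterated to a fixed point so that trimming is idempotent: a single pass
is not, in the rare case where the trimmed read's own 3' end happens to
resemble a short adapter prefix.

**Annotation.** Phase 1 enumerates every ungapped sense-strand
placement of the whole read *inside* each mature reference (so reads no
longer than a reference, including exact-length reads at offset 0) and
keeps the placement with the fewest mismatches (≤ 2). Reads that fail —
typically 3'-extended isomiRs longer than every mature sequence, which
a conventional short-read aligner cannot place — are rescued in phase 2
by placing each mature sequence *inside* the read. Ties are broken by
mismatch count, then smaller offset, then reference file order;
residual ties (e.g. family members sharing a seed) are flagged in the
`tie` column and the first hit is kept, with a message reporting how
many reads were ambiguous. Counts plus unassigned always equal the
number of preprocessed reads. Quality strings are carried through
untouched; they play no role in filtering.

# Seed sites, mutagenesis, and sponge design

The seed is miRNA positions 2–8 (5'→3'). On the UTR (sense strand,
0-based half-open coordinates) the scanner reports canonical classes:
**7mer-m8** (reverse complement of positions 2–8), **8mer** (the same
followed by an `A` opposite miRNA position 1), and **7mer-A1** (reverse
complement of positions 2–7 plus that `A`). Each seed match is reported
once with its best class — the 6-mer core inside a 7mer-m8/8mer match is
the same physical site, not an additional one. Overlapping distinct
matches are all reported; `N` never matches; no G:U wobble is allowed.

`mutate_site()` substitutes `n_mut` (default 3) positions inside the
seed-pairing core using deterministic transversions (A↔C, G↔T) of the
current base, which always breaks Watson–Crick pairing, then verifies by
rescanning that no site overlapping the original window survives,
re-drawing the mutated positions if a shifted match does (bounded,
seeded retry). The Hamming distance between input and output is exactly
`n_mut`.

`design_sponge()` builds tandem bulged binding sites: each site is the
reverse complement of the full mature sequence with the four positions
pairing miRNA nucleotides 9–12 — immediately 3' of the seed —
substituted by the same transversion rule so they cannot pair. The
central bulge favors stable sequestration of the miRNA over
Ago2-mediated slicing of the decoy. "Immediately after the seed" is
interpreted as substitution (a bulge), not insertion, and positions
9–12 on the miRNA. Sites are joined by a spacer (default `CATT`); the
finished construct is rescanned and must contain exactly `repeats` seed
sites at the recorded coordinates — if a junction creates a spurious
site another spacer from a fixed list is tried deterministically, and a
mature sequence whose own complement contains extra internal seed
matches is rejected with an error rather than silently emitting a
construct that violates the invariant. The exact spacer and bulge bases
are this package's deterministic choices; equivalent constructs exist.

# The anticorrelation statistic

For a target set *T*, `target_correlations()` computes the Pearson
correlation of each target with the miRNA, by default across all 25
samples (`per-sample`); a `per-age-mean` layout that first averages
replicates within each age is available, since published figures of
this kind do not always state which layout was used. `bootstrap_null()`
draws `B = 1000` size-matched sets of non-target genes (without
replacement within a draw, independently across draws) and pools their
correlations. Resampling genes — rather than samples or correlation
values — is the package's choice of bootstrap unit. Because a gene's
correlation with the miRNA is a fixed quantity, the pool of non-target
correlations is computed once and draws index into it; this is
statistically identical to recomputing per draw and keeps 500-replicate
calibration runs fast.

`ks_compare()` computes the two-sample Kolmogorov–Smirnov statistic
*D* = sup |ECDF difference| between target and pooled null
correlations. One numerical subtlety matters: the pooled bootstrap has
length *B*·|*T*| but carries at most one distinct value per non-target
gene, so feeding its raw length into the KS p-value overstates the
null information and is anti-conservative (about 10% rejection at
α = 0.05 under the default 1000-gene conditions). `anticorr_test()`
therefore passes the non-target pool size as the effective null sample
size and the p-value uses the asymptotic two-sample formula with
*nm*/(*n*+*m*). The default test is two-sided; a one-sided
`targets-less` alternative (targets shifted toward negative
correlations) is available by flag, as the direction-specific question
is often the one of interest. Pooled draws necessarily repeat values;
the tie warning from the underlying test is suppressed for that known
reason, and the asymptotic (not exact) p-value is always used.

Under the default conditions the suite verifies calibration (null
rejection ≤ 0.05 + 2·MC-SE over 500 replicates) and power (≥ 0.9 at
coupling 1, noise 0.3, 200 targets, 25 samples; empirically 1.0).

# Target overrepresentation with triple-test consensus

`enrichment_tests()` evaluates the overlap *k* between a gene cluster
(size *n*) and a target set (size *K*) in a universe (size *N*) with
three one-sided tests on the same 2×2 table: binomial (*k* successes in
*n* draws at rate *K*/*N*), Fisher's exact, and the hypergeometric
upper tail. One-sided Fisher and the hypergeometric tail are
mathematically identical, which the tests assert to 10⁻¹²; the binomial
is the approximation that ignores finite-universe depletion. Per test,
p-values are Hochberg-adjusted **across miRNAs**, and a miRNA's targets
are called overrepresented only when **all three** adjusted p-values
fall below α = 0.05. The conjunction plus Hochberg keeps the
family-wise false-consensus rate on random clusters below α
(empirically ≈ 0.02–0.04 over 500 replicates with 20 miRNAs).

# DEG-intersection concordance typing

Genes differentially expressed in both an aging contrast and a sponge
contrast (FDR < 0.05 each) are typed by the signs of their log2 fold
changes: type 1 up/up, type 2 up in aging but down in sponge, type 3
down/down, type 4 down in aging but up in sponge. Types 1 and 3 are
concordant — the sponge recapitulates the aging direction. Percentages
are rounded to the nearest integer. Direction is the sign of log2FC;
a zero fold change has no direction, so such genes are excluded with a
warning rather than guessed (published totals of this kind can differ
by one from the sum of typed genes for exactly this sort of edge case;
`concordance()` reports the classified count and accepts a
`total_override` denominator so both totals are visible). Independence
of the two direction labels is tested with a 2×2 χ² without continuity
correction (the counts in this design are large); when any expected
cell drops below 5 a Fisher exact test is substituted and flagged in
`test_used`. `overlap_fisher()` provides the companion two-sided Fisher
test for overlap between DEG sets and externally supplied
trait-associated gene lists (e.g. lifespan-correlated genes), reporting
the sample odds ratio; the choice of universe is the caller's and
materially affects the result.

# Numerical and interface choices

* Coordinates are 0-based half-open on the sense strand throughout;
  FASTA/FASTQ ids are the first whitespace token; RNA input (`U`) is
  normalized to `T` on load and flagged.
* FASTQ is plain 4-line Sanger/Phred+33; malformed records raise
  errors naming the offending record.
* All Monte-Carlo machinery takes explicit integer seeds; pipeline
  provenance records package version, a configuration hash, and the
  seed, and reruns with an identical configuration are byte-identical.
* Problem sizes in the shipped validation suite (1000 genes, 200
  targets, 25 samples, B = 1000, 500 calibration replicates, 200
  random annotator instances of up to 100 reads × 10 references) were
  chosen as the smallest sizes at which the statistical properties
  under test are stable.

# Known limitations

The annotator is ungapped and sense-strand only, by design — it
quantifies known matures and length isomiRs, not novel miRNAs or edited
variants. The scanner knows nothing of site context (AU flank, position
in UTR) or pairing thermodynamics; it is a seed matcher, and target
*prediction* is consumed, not produced. The enrichment module offers
only Hochberg for the consensus step. The generator's independence
assumptions (genes independent given the miRNA) make the calibration
results a best case; correlated gene modules in real data would widen
the null.
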