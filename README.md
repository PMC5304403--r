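# miraging

Tools for studying age-regulated microRNAs in brain transcriptome data,
built around the miR-29/aging analysis workflow: does a miRNA that
rises with age repress its predicted targets, and does antagonizing it
with a sponge transgene push gene expression in the same direction as
aging itself?

The package implements five connected pieces:

1. **Small RNA-seq annotation** — N-filtering, mismatch-tolerant 3'
   adapter trimming (adapter `TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC`, up to
   two mismatches, prorated for short overlaps), 18–33 nt size
   selection, and a two-phase ungapped aligner: reads are first placed
   *inside* mature miRNA references (≤ 2 mismatches); reads longer than
   every reference — 3'-extended isomiRs — are rescued by placing the
   mature sequences *inside* the read.
2. **Seed-site tools** — a canonical 8mer/7mer-m8/7mer-A1 scanner for
   seed matches (miRNA positions 2–8) on 3'-UTRs, deterministic 3-nt
   binding-site mutagenesis, and bulged sponge construct design: seven
   tandem reverse-complement sites with the four bases pairing miRNA
   positions 9–12 (immediately after the seed) made non-complementary.
3. **Target anticorrelation** — per-target Pearson correlation with
   miRNA expression across an age series, a size-matched bootstrap null
   of non-target genes (B = 1000, pooled), and a two-sample
   Kolmogorov–Smirnov comparison

   D = sup_x | F̂_targets(x) − F̂_null(x) |,

   with the p-value computed at the effective null sample size (the
   non-target pool, not the inflated pooled length).
4. **Target overrepresentation** — one-sided binomial, Fisher and
   hypergeometric tests on the cluster × target 2×2 table, Hochberg
   correction across miRNAs per test, and a consensus call requiring
   all three adjusted p-values < 0.05.
5. **DEG-intersection concordance** — genes significant in both an
   aging contrast and a sponge contrast are typed by fold-change signs
   (type 1 up/up, type 2 up/down, type 3 down/down, type 4 down/up);
   types 1+3 are concordant; independence is tested by 2×2 χ² (Fisher
   fallback for small cells), plus fold-change correlation and Fisher
   overlap with external trait gene sets.

A seeded synthetic-data generator (`sim_config()`,
`simulate_expression()`, `simulate_deg_tables()`,
`simulate_smallrna_reads()`, `simulate_utrs()`) emulates the study
design — five age groups × five replicates, a miRNA rising 15-fold with
age, 200 negatively coupled targets, adapter-ligated isomiR reads —
so the whole pipeline is testable end to end. `run_pipeline()` drives
all stages against one configuration and writes provenance.

## Worked example

```r
library(miraging)

## age-series simulation under default study conditions
se  <- simulate_expression(sim_config(rng_seed = 1))
res <- anticorr_test(se$expr, se$mirna, se$truth$target_gene_ids,
                     anticorr_config(B = 1000, rng_seed = 1))
res
#> Target anticorrelation: 200 targets (median r = -0.713), null n = 200000 (median r = -0.028)
#>   KS D = 0.9987, p = 4.83e-139
```

Targets sit far to the left of the bootstrap null (median r −0.71
versus −0.03): the simulated repression is detected essentially
perfectly, and under a null simulation (`coupling = 0`) the same test
rejects at close to its nominal 5% rate.

```r
## concordance typing of the aging x sponge DEG intersection
dg <- simulate_deg_tables(c(225, 34, 231, 34), c(50, 50),
                          sim_config(rng_seed = 1))
concordance(classify_types(dg$aging, dg$sponge), total_override = 525)
#> DEG intersection concordance: 456/525 concordant (~87%), 69 discordant (~13%)
#>   types 1-4: 225, 34, 231, 34; chisq p = 1.95e-64
```

456 of the intersected genes (~87%) move in the same direction in
aging and under miRNA antagonism — the sponge partially recapitulates
the aging signature; the χ² test rejects independence of the two
direction labels.

```r
## sponge design and rescan
sp <- design_sponge(seed_definition("TAGCACCATTTGAAATCGGTTA"))
sp
#> miRNA sponge: 7 bulged sites, spacer 'CATT', 178 nt
nrow(scan_utr(sp$sequence, seed_definition("TAGCACCATTTGAAATCGGTTA")))
#> [1] 7

## small-RNA annotation of simulated reads
ref <- c(mir29a = "TAGCACCATTTGAAATCGGTTA",
         mir29b = "TAGCACCATTTGAAATCAGTGTT")
sr  <- simulate_smallrna_reads(ref, sim_config(read_count = 1000, rng_seed = 1))
ann <- annotate_reads(preprocess_reads(sr$reads)$reads, ref)
ann
#> Two-phase small-RNA annotation
#>   assigned: 946 (phase 1: 668, phase 2: 278), unassigned: 0
ann$counts
#> mir29a mir29b
#>    471    475
```

All preprocessed reads are assigned (278 of them only by the phase-2
rescue of 3'-extended isomiRs), and per-miRNA counts match the
generator's ground truth.

See `vignettes/mirna-aging-methods.Rmd` for the full model
description, parameter meanings, and design choices.

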