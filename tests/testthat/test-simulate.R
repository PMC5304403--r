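# Synthetic-data generator: effect recovery, determinism, conservation.

test_that("miRNA trajectory recovers the configured fold change exactly at zero noise", {
  cfg <- sim_config(noise_sigma = 0, coupling = 0, n_genes = 40,
                    n_targets = 10, mirna_fold_change = 15)
  se <- simulate_expression(cfg)
  young <- mean(se$mirna[se$samples$age_weeks == min(cfg$ages)])
  old <- mean(se$mirna[se$samples$age_weeks == max(cfg$ages)])
  expect_equal(old / young, 15)
  # monotone rise of per-age means
  means <- tapply(se$mirna, se$samples$age_weeks, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
  # zero coupling, zero noise: every gene constant across samples
  expect_true(all(apply(se$expr, 1, function(v) max(v) - min(v)) == 0))
  expect_true(all(se$expr >= 0))
})

test_that("targets are negatively coupled to the miRNA (direct Pearson oracle)", {
  cfg <- sim_config(coupling = 1, noise_sigma = 0.1, n_genes = 120,
                    n_targets = 30, rng_seed = 1)
  se <- simulate_expression(cfg)
  r <- vapply(se$truth$target_gene_ids, function(g) {
    oracle_pearson(se$expr[g, ], as.numeric(se$mirna))
  }, numeric(1))
  expect_lt(mean(r), 0)
  # package correlations agree with the direct formula
  rt <- target_correlations(se$expr, se$mirna, se$truth$target_gene_ids)
  expect_equal(unname(rt), unname(r[names(rt)]), tolerance = 1e-12)
})

test_that("simulation is deterministic and conserves configured sizes", {
  cfg <- sim_config(n_genes = 80, n_targets = 20, read_count = 150,
                    rng_seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$expr), 80)
  expect_equal(ncol(a$expr), length(cfg$ages) * cfg$n_per_age)
  expect_true(all(a$truth$target_gene_ids %in% rownames(a$expr)))

  ref <- c(mir29a = MIR29A)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  simulate_smallrna_reads(ref, cfg, f1)
  simulate_smallrna_reads(ref, cfg, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(read_fastq(f1)), 150)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 10, n_targets = 11), "n_targets")
  expect_error(sim_config(mirna_fold_change = 0), "fold_change")
  expect_error(sim_config(error_rate = 1.2), "error_rate")
  expect_error(sim_config(isomir_len_shift = c("0" = 0.5, "1" = 0.2)),
               "sum to 1")
  expect_error(
    simulate_smallrna_reads(c(x = "ACGU"), sim_config()), "contains")
})

test_that("error-free, shift-free reads reduce to their mature sequence", {
  cfg <- sim_config(read_count = 60, error_rate = 0, n_rate = 0,
                    isomir_len_shift = c("0" = 1), rng_seed = 7)
  ref <- c(mir29a = MIR29A, mir29b = "TAGCACCATTTGAAATCAGTGTT")
  sr <- simulate_smallrna_reads(ref, cfg)
  pp <- preprocess_reads(sr$reads)
  expect_equal(nrow(pp$reads), 60)
  expect_identical(unname(pp$reads$seq),
                   unname(ref[sr$truth$mirna_id]))
})

test_that("+4 isomiR shift yields trimmed reads longer than the 22-nt mature", {
  cfg <- sim_config(read_count = 20, error_rate = 0, n_rate = 0,
                    isomir_len_shift = c("4" = 1), rng_seed = 3)
  sr <- simulate_smallrna_reads(c(mir29a = MIR29A), cfg)
  pp <- preprocess_reads(sr$reads)
  expect_true(all(nchar(pp$reads$seq) == 26))
  ann <- annotate_reads(pp$reads, c(mir29a = MIR29A))
  expect_true(all(ann$assignments$phase == 2))
})

test_that("DEG tables realize requested type composition and overlap structure", {
  dg <- simulate_deg_tables(c(3, 2, 4, 1), extra_nonoverlap = c(5, 6),
                            config = sim_config(rng_seed = 11))
  expect_equal(length(intersect_degs(dg$aging, dg$sponge)), 10)
  expect_equal(nrow(dg$aging), 15)
  expect_equal(nrow(dg$sponge), 16)
  expect_true(all(abs(c(dg$aging$log2FC, dg$sponge$log2FC)) >= 0.1))
  expect_true(all(c(dg$aging$FDR, dg$sponge$FDR) < 0.05))
  # empty intersection case
  d0 <- simulate_deg_tables(c(0, 0, 0, 0), c(10, 10))
  expect_length(intersect_degs(d0$aging, d0$sponge), 0)
})

test_that("planted UTR sites are recovered and absent sites stay absent", {
  sd1 <- seed_definition(MIR29A)
  su <- simulate_utrs(4, sd1,
                      planted_sites = data.frame(
                        utr = c(1, 2, 2), pos = c(10, 5, 40),
                        class = c("8mer", "7mer-m8", "7mer-A1")),
                      utr_length = 60, rng_seed = 5)
  hits <- scan_utrs(su$utrs, sd1)
  expect_equal(nrow(hits), 3)
  expect_equal(hits[hits$utr_id == "utr0001", "start"], 10)
  expect_equal(hits[hits$utr_id == "utr0001", "end"], 18)
  expect_equal(hits[hits$utr_id == "utr0001", "class"], "8mer")
  expect_setequal(hits[hits$utr_id == "utr0002", "start"], c(5, 40))
  # UTRs without planted sites scan clean
  expect_equal(nrow(scan_utr(su$utrs[["utr0003"]], sd1)), 0)
  # n = 0 gives an empty FASTA-able set
  expect_length(simulate_utrs(0, sd1)$utrs, 0)
})
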