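# Preprocessing and two-phase annotation.

test_that("N-containing reads are eliminated, order preserved", {
  rs <- read_set(c("a", "b", "c"), c("ACGT", "ACNT", "NNNN"))
  out <- filter_n(rs)
  expect_identical(out$id, "a")
  expect_identical(filter_n(rs[0, ]), rs[0, ])
  clean <- read_set(c("x", "y"), c("ACGT", "TTTT"))
  expect_identical(filter_n(clean), clean)
})

test_that("adapter trimming removes adapter-prefix suffixes within the prorated budget", {
  core <- "TAGCACCATTTGAAATCGGTTA"
  p <- preprocess_params()
  # full adapter appended
  rs <- read_set("r1", paste0(core, ADAPTER))
  expect_identical(trim_adapter(rs, p)$seq, core)
  # quality trimmed in lockstep
  expect_equal(nchar(trim_adapter(rs, p)$qual), nchar(core))
  # 12-nt overlap tolerates 1 substitution (budget floor(12/8) = 1)
  ad12 <- substr(ADAPTER, 1, 12)
  substr(ad12, 5, 5) <- if (substr(ad12, 5, 5) == "A") "C" else "A"
  expect_identical(trim_adapter(read_set("r2", paste0(core, ad12)), p)$seq,
                   core)
  # 16-nt overlap tolerates 2 substitutions
  ad16 <- substr(ADAPTER, 1, 16)
  substr(ad16, 3, 3) <- if (substr(ad16, 3, 3) == "G") "T" else "G"
  substr(ad16, 9, 9) <- if (substr(ad16, 9, 9) == "G") "T" else "G"
  expect_identical(trim_adapter(read_set("r3", paste0(core, ad16)), p)$seq,
                   core)
  # no adapter signal: unchanged
  rs4 <- read_set("r4", "ACGTACGTACGTACGTACGT")
  expect_identical(trim_adapter(rs4, p), rs4)
})

test_that("trimming matches the brute-force overlap oracle and is idempotent", {
  set.seed(101)
  p <- preprocess_params()
  for (i in 1:60) {
    core <- random_seq(sample(15:30, 1))
    kind <- sample(1:3, 1)
    seq <- switch(kind,
                  paste0(core, ADAPTER),                       # full
                  paste0(core, substr(ADAPTER, 1, sample(1:20, 1))),  # prefix
                  core)                                        # none
    if (runif(1) < 0.5) seq <- substitute_bases(seq, sample(1:2, 1))
    got <- trim_adapter(read_set("r", seq), p)$seq
    expect_identical(got, oracle_trim(seq, ADAPTER))
    expect_identical(trim_adapter(read_set("r", got), p)$seq, got)
  }
})

test_that("length filter keeps the 18-33 nt window inclusively", {
  rs <- read_set(paste0("r", 1:4),
                 vapply(c(17, 18, 33, 34), random_seq, character(1)))
  kept <- filter_length(rs)
  expect_identical(kept$id, c("r2", "r3"))
  rs22 <- read_set(paste0("q", 1:3), vapply(rep(22, 3), random_seq,
                                            character(1)))
  expect_identical(filter_length(rs22), rs22)
  expect_equal(nrow(filter_length(rs[0, ])), 0)
})

test_that("phase-1 alignment finds the best whole-read placement", {
  ref <- mature_reference(c(m1 = MIR29A, m2 = "TAGCACCATTTGAAATCAGTGTT"))
  a <- align_phase1(list(id = "r", seq = MIR29A), ref)
  expect_equal(a$mirna_id, "m1")
  expect_equal(a$mismatches, 0)
  expect_equal(a$offset, 0)
  expect_equal(a$phase, 1)
  # 20-nt prefix with 2 substitutions
  set.seed(2)
  rd <- substitute_bases(substr(MIR29A, 1, 20), 2)
  a2 <- align_phase1(list(id = "r", seq = rd), ref)
  expect_equal(a2$mismatches, 2)
  # >2 mismatches: unassigned
  rd3 <- "GGGGGGGGGGGGGGGGGGGG"
  expect_null(align_phase1(list(id = "r", seq = rd3), ref))
})

test_that("phase-2 alignment places mature sequences inside long reads", {
  ref <- mature_reference(c(m1 = MIR29A))
  long <- paste0("GT", MIR29A, "CA")
  a <- align_phase2(list(id = "r", seq = long), ref)
  expect_equal(a$offset, 2)
  expect_equal(a$mismatches, 0)
  expect_equal(a$phase, 2)
  # read shorter than every mature: no phase-2 placement
  expect_null(align_phase2(list(id = "r", seq = "ACGTACGTACGT"), ref))
  set.seed(3)
  long2 <- paste0(random_seq(4), substitute_bases(MIR29A, 2),
                  random_seq(4))
  a2 <- align_phase2(list(id = "r", seq = long2), ref)
  expect_equal(a2$mismatches, 2)
})

test_that("annotation recovers generator ground truth at zero error rate", {
  cfg <- sim_config(read_count = 120, error_rate = 0, n_rate = 0,
                    rng_seed = 9)
  ref <- c(mir29a = MIR29A, mir29b = "TAGCACCATTTGAAATCAGTGTT")
  sr <- simulate_smallrna_reads(ref, cfg)
  pp <- preprocess_reads(sr$reads)
  ann <- annotate_reads(pp$reads, ref)
  expect_equal(ann$unassigned, 0)
  truth_counts <- table(sr$truth$mirna_id[sr$truth$read_id %in%
                                            pp$reads$id])
  expect_equal(as.integer(ann$counts[names(truth_counts)]),
               as.integer(truth_counts))
})

test_that("annotation conserves reads, is monotone in max_mm, matches the oracle", {
  set.seed(77)
  for (i in 1:8) {
    inst <- random_annot_instance(max_reads = 40, max_refs = 5)
    ann <- annotate_reads(inst$reads, inst$ref)
    expect_equal(nrow(ann$assignments) + ann$unassigned,
                 nrow(inst$reads))
    expect_equal(sum(ann$counts) + ann$unassigned, nrow(inst$reads))
    expect_lte(max(table(ann$assignments$read_id), 0), 1)
    oc <- oracle_annotate(inst$reads, inst$ref)
    expect_equal(ann$assignments[, names(oc)], oc)
    # widening the mismatch budget never loses assignments
    ann3 <- annotate_reads(inst$reads, inst$ref, max_mm = 3)
    expect_gte(nrow(ann3$assignments), nrow(ann$assignments))
  }
})

test_that("degenerate annotation inputs are handled", {
  ref <- c(m1 = MIR29A)
  # single read equal to the single reference
  ann <- annotate_reads(read_set("r1", MIR29A), ref)
  expect_equal(as.integer(ann$counts), 1)
  expect_equal(ann$unassigned, 0)
  # unalignable random 33-mers
  set.seed(5)
  far <- read_set(paste0("r", 1:10),
                  vapply(rep(33, 10), function(n) {
                    paste(sample(c("C", "G"), n, TRUE), collapse = "")
                  }, character(1)))
  ann2 <- annotate_reads(far, ref)
  expect_equal(ann2$unassigned, 10)
  # N after preprocessing is a defensive error
  expect_error(annotate_reads(read_set("r1", "ACGTNACGTACGTACGTACGT"),
                              ref), "contains N")
  expect_error(mature_reference(character(0)), "empty")
})
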