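# Synthetic-data generator: seeded simulations of the age-series study
# design used to validate every downstream stage.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study design the analysis assumes: five age groups spanning sexual
#' maturity to exceptional survivors with five animals per age, a miRNA
#' whose mean expression rises 15-fold between the youngest and oldest
#' group, and a target set repressed in proportion to the (standardized,
#' log-scale) miRNA level.
#'
#' @param ages Ordered numeric vector of age labels in weeks.
#' @param n_per_age Replicates (animals) per age group.
#' @param n_genes Number of simulated genes.
#' @param n_targets Number of genes coupled (negatively) to the miRNA.
#' @param mirna_fold_change Ratio of oldest/youngest mean miRNA expression
#'   (unitless, > 0).
#' @param coupling Repression strength: log2 units of target expression
#'   lost per standard deviation of log2 miRNA expression.
#' @param noise_sigma Standard deviation of the multiplicative log-normal
#'   noise (natural-log scale) applied to every expression value.
#' @param base_mirna Mean miRNA expression (RPKM-like) in the youngest group.
#' @param read_count Number of small-RNA reads to emit.
#' @param error_rate Per-base substitution probability in simulated reads.
#' @param n_rate Per-base probability of an 'N' call in simulated reads.
#' @param adapter 3' sequencing adapter appended to every simulated read.
#' @param isomir_len_shift Named numeric vector: probability distribution
#'   over 3' length offsets relative to the mature sequence (names are
#'   integer offsets; positive offsets yield reads longer than their
#'   source mature miRNA after trimming).
#' @param read_length Fixed raw read length (nt) emitted by the simulated
#'   sequencer; insert plus adapter is truncated to this length.
#' @param rng_seed Integer seed; identical configurations give
#'   byte-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(ages = c(5, 12, 20, 27, 39),
                       n_per_age = 5L,
                       n_genes = 1000L,
                       n_targets = 200L,
                       mirna_fold_change = 15,
                       coupling = 1,
                       noise_sigma = 0.3,
                       base_mirna = 50,
                       read_count = 1000L,
                       error_rate = 0.001,
                       n_rate = 0.001,
                       adapter = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                       isomir_len_shift = c("-2" = 0.05, "-1" = 0.10,
                                            "0" = 0.55, "1" = 0.15,
                                            "2" = 0.10, "3" = 0.03,
                                            "4" = 0.02),
                       read_length = 50L,
                       rng_seed = 1L) {
  cfg <- list(ages = as.numeric(ages), n_per_age = as.integer(n_per_age),
              n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
              mirna_fold_change = mirna_fold_change, coupling = coupling,
              noise_sigma = noise_sigma, base_mirna = base_mirna,
              read_count = as.integer(read_count), error_rate = error_rate,
              n_rate = n_rate, adapter = adapter,
              isomir_len_shift = isomir_len_shift,
              read_length = as.integer(read_length),
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$ages) >= 2L, !is.unsorted(cfg$ages))
  if (cfg$n_per_age < 1L) stop("n_per_age must be >= 1", call. = FALSE)
  if (cfg$n_targets > cfg$n_genes) {
    stop("n_targets must not exceed n_genes", call. = FALSE)
  }
  if (cfg$mirna_fold_change <= 0) {
    stop("mirna_fold_change must be > 0", call. = FALSE)
  }
  for (r in c("error_rate", "n_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop(sprintf("%s must lie in [0, 1]", r), call. = FALSE)
    }
  }
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  check_dna(cfg$adapter, "adapter")
  p <- cfg$isomir_len_shift
  if (is.null(names(p)) || any(is.na(suppressWarnings(as.integer(names(p)))))) {
    stop("isomir_len_shift must be named by integer offsets", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("isomir_len_shift probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate an age-series expression matrix with a rising miRNA
#'
#' Generates a gene-by-sample RPKM-like matrix over `length(ages) *
#' n_per_age` samples. The miRNA mean follows a geometric interpolation
#' from `base_mirna` in the youngest group to `base_mirna *
#' mirna_fold_change` in the oldest, so with `noise_sigma = 0` the
#' oldest/youngest mean ratio equals `mirna_fold_change` exactly. A random
#' subset of `n_targets` genes is repressed by `-coupling` log2 units per
#' standard deviation of the (log2) miRNA level; the remaining genes are
#' independent of the miRNA. All values are multiplied by log-normal noise
#' and remain nonnegative.
#'
#' Draw order (fixed for reproducibility): per-sample miRNA noise, gene
#' baselines, target-gene sampling, then the gene-by-sample noise matrix.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_expression` with elements `expr`
#'   (genes-by-samples numeric matrix), `samples` (data.frame: sample_id,
#'   age_weeks, replicate), `mirna` (per-sample miRNA expression vector),
#'   and `truth` (list with `target_gene_ids`).
#' @export
simulate_expression <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$rng_seed, {
    n_age <- length(config$ages)
    n_samp <- n_age * config$n_per_age
    age_idx <- rep(seq_len(n_age), each = config$n_per_age)
    samples <- data.frame(
      sample_id = sprintf("s%02d_age%g_r%d", seq_len(n_samp),
                          config$ages[age_idx],
                          rep(seq_len(config$n_per_age), times = n_age)),
      age_weeks = config$ages[age_idx],
      replicate = rep(seq_len(config$n_per_age), times = n_age),
      stringsAsFactors = FALSE
    )
    # geometric interpolation of the miRNA mean across age groups
    mu_age <- config$base_mirna *
      config$mirna_fold_change^((seq_len(n_age) - 1) / (n_age - 1))
    mirna <- mu_age[age_idx] * exp(stats::rnorm(n_samp, 0, config$noise_sigma))
    names(mirna) <- samples$sample_id

    gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
    baseline <- exp(stats::rnorm(config$n_genes, log(10), 1))
    target_ids <- sort(sample(gene_ids, config$n_targets))
    is_target <- gene_ids %in% target_ids

    lm2 <- log2(mirna)
    z <- if (stats::sd(lm2) > 0) as.numeric(scale(lm2)) else rep(0, n_samp)
    noise <- matrix(exp(stats::rnorm(config$n_genes * n_samp, 0,
                                     config$noise_sigma)),
                    nrow = config$n_genes)
    expr <- baseline * noise
    if (any(is_target)) {
      rep_factor <- matrix(2^(-config$coupling * z),
                           nrow = sum(is_target), ncol = n_samp, byrow = TRUE)
      expr[is_target, ] <- expr[is_target, , drop = FALSE] * rep_factor
    }
    dimnames(expr) <- list(gene_ids, samples$sample_id)
    structure(list(expr = expr, samples = samples, mirna = mirna,
                   truth = list(target_gene_ids = target_ids)),
              class = "sim_expression")
  })
}

#' Simulate paired differential-expression tables with typed overlap
#'
#' Builds two DEG tables (an "aging" contrast and a "sponge" contrast)
#' whose intersection contains exactly the requested number of genes of
#' each concordance type: type 1 up/up, type 2 up in aging and down in
#' sponge, type 3 down/down, type 4 down in aging and up in sponge.
#' Additional genes unique to each table can be added. Fold-change
#' magnitudes are drawn as |N(1, 0.25)| floored at 0.1 so signs are
#' unambiguous; all rows pass FDR < 0.05.
#'
#' @param type_counts Integer vector of length 4: genes of types 1-4 in
#'   the intersection.
#' @param extra_nonoverlap Integer vector of length 2: genes present only
#'   in the aging table, and only in the sponge table.
#' @param config A [sim_config()] (only the seed is used).
#' @return A list of class `sim_deg` with `aging` and `sponge` DEG
#'   data.frames (gene_id, log2FC, PValue, FDR) and `truth`
#'   (data.frame gene_id, type for the intersection).
#' @export
simulate_deg_tables <- function(type_counts,
                                extra_nonoverlap = c(0L, 0L),
                                config = sim_config()) {
  stopifnot(length(type_counts) == 4L, all(type_counts >= 0),
            length(extra_nonoverlap) == 2L, all(extra_nonoverlap >= 0))
  type_counts <- as.integer(type_counts)
  extra_nonoverlap <- as.integer(extra_nonoverlap)
  with_seed(config$rng_seed, {
    n_int <- sum(type_counts)
    types <- rep(1:4, times = type_counts)
    int_ids <- sprintf("ixgene%05d", seq_len(n_int))
    # sign table: aging, sponge by type
    aging_sign <- c(1, 1, -1, -1)[types]
    sponge_sign <- c(1, -1, -1, 1)[types]
    fc_mag <- function(n) pmax(0.1, abs(stats::rnorm(n, 1, 0.25)))
    deg_row <- function(ids, sign, n) {
      data.frame(gene_id = ids, log2FC = sign * fc_mag(n),
                 PValue = stats::runif(n, 0, 1e-3),
                 FDR = stats::runif(n, 0, 0.049),
                 stringsAsFactors = FALSE)
    }
    aging <- deg_row(int_ids, aging_sign, n_int)
    sponge <- deg_row(int_ids, sponge_sign, n_int)
    if (extra_nonoverlap[1] > 0L) {
      ids <- sprintf("aggene%05d", seq_len(extra_nonoverlap[1]))
      sgn <- sample(c(-1, 1), extra_nonoverlap[1], replace = TRUE)
      aging <- rbind(aging, deg_row(ids, sgn, extra_nonoverlap[1]))
    }
    if (extra_nonoverlap[2] > 0L) {
      ids <- sprintf("spgene%05d", seq_len(extra_nonoverlap[2]))
      sgn <- sample(c(-1, 1), extra_nonoverlap[2], replace = TRUE)
      sponge <- rbind(sponge, deg_row(ids, sgn, extra_nonoverlap[2]))
    }
    structure(list(aging = aging, sponge = sponge,
                   truth = data.frame(gene_id = int_ids, type = types,
                                      stringsAsFactors = FALSE)),
              class = "sim_deg")
  })
}

#' Simulate adapter-ligated small-RNA reads from a mature reference
#'
#' Each read is built from a randomly chosen mature miRNA, its 3' end
#' shifted by an offset drawn from `isomir_len_shift` (positive offsets
#' add random untemplated bases, emulating 3' isomiRs longer than the
#' reference), followed by the 3' adapter; the result is truncated to
#' `read_length`, then per-base substitution errors and 'N' calls are
#' applied at the configured rates. Qualities are constant Phred 40
#' ("I"), Sanger encoded.
#'
#' @param ref Named character vector of mature miRNA sequences (ACGT).
#' @param config A [sim_config()].
#' @param path Optional FASTQ output path; when given the reads are also
#'   written with [write_fastq()].
#' @return A list of class `sim_reads`: `reads` (data.frame id, seq,
#'   qual) and `truth` (data.frame read_id, mirna_id, shift,
#'   insert_length).
#' @export
simulate_smallrna_reads <- function(ref, config = sim_config(), path = NULL) {
  if (length(ref) == 0L) stop("mature reference is empty", call. = FALSE)
  if (is.null(names(ref)) || anyDuplicated(names(ref))) {
    stop("reference sequences must have unique names", call. = FALSE)
  }
  for (i in seq_along(ref)) check_dna(ref[[i]], names(ref)[i])
  validate_sim_config(config)
  with_seed(config$rng_seed, {
    n <- config$read_count
    shifts <- as.integer(names(config$isomir_len_shift))
    src <- names(ref)[sample.int(length(ref), n, replace = TRUE)]
    shift <- shifts[sample.int(length(shifts), n, replace = TRUE,
                               prob = config$isomir_len_shift)]
    seqs <- character(n)
    ins_len <- integer(n)
    for (i in seq_len(n)) {
      m <- ref[[src[i]]]
      core <- if (shift[i] < 0L) {
        substr(m, 1L, nchar(m) + shift[i])
      } else if (shift[i] > 0L) {
        paste0(m, paste(sample(DNA_BASES, shift[i], replace = TRUE),
                        collapse = ""))
      } else m
      ins_len[i] <- nchar(core)
      full <- paste0(core, config$adapter)
      seqs[i] <- substr(full, 1L, min(nchar(full), config$read_length))
    }
    # substitution errors, then N calls
    if (config$error_rate > 0 || config$n_rate > 0) {
      for (i in seq_len(n)) {
        ch <- strsplit(seqs[i], "")[[1]]
        if (config$error_rate > 0) {
          hit <- which(stats::runif(length(ch)) < config$error_rate)
          for (j in hit) {
            ch[j] <- sample(setdiff(DNA_BASES, ch[j]), 1L)
          }
        }
        if (config$n_rate > 0) {
          ch[stats::runif(length(ch)) < config$n_rate] <- "N"
        }
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    reads <- data.frame(id = sprintf("read%06d", seq_len(n)),
                        seq = seqs,
                        qual = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = reads$id, mirna_id = src, shift = shift,
                        insert_length = ins_len, stringsAsFactors = FALSE)
    out <- structure(list(reads = reads, truth = truth), class = "sim_reads")
    if (!is.null(path)) write_fastq(reads, path)
    out
  })
}

#' Simulate 3'-UTR sequences with planted miRNA seed sites
#'
#' Generates uniform-composition random UTRs and plants canonical seed
#' sites (8mer, 7mer-m8, 7mer-A1) for the given miRNA at requested
#' 0-based positions. Backgrounds are rejection-sampled so that scanning
#' each UTR reports exactly the planted sites and nothing else.
#'
#' @param n Number of UTRs.
#' @param seed A [seed_definition()].
#' @param planted_sites NULL or a data.frame with columns `utr` (1-based
#'   UTR index), `pos` (0-based site start), `class` (one of "8mer",
#'   "7mer-m8", "7mer-A1").
#' @param utr_length UTR length in nt (scalar or length-n vector).
#' @param rng_seed Integer seed.
#' @return A list of class `sim_utrs`: `utrs` (named character vector)
#'   and `truth` (data.frame utr_id, start, end, class; empty when no
#'   sites are planted).
#' @export
simulate_utrs <- function(n, seed, planted_sites = NULL, utr_length = 80L,
                          rng_seed = 1L) {
  stopifnot(n >= 0L)
  utr_length <- rep_len(as.integer(utr_length), max(n, 1L))
  if (!is.null(planted_sites)) {
    stopifnot(all(c("utr", "pos", "class") %in% names(planted_sites)),
              all(planted_sites$utr >= 1L), all(planted_sites$utr <= n),
              all(planted_sites$class %in% c("8mer", "7mer-m8", "7mer-A1")))
  }
  ids <- sprintf("utr%04d", seq_len(n))
  if (n == 0L) {
    return(structure(list(
      utrs = stats::setNames(character(0), character(0)),
      truth = data.frame(utr_id = character(0), start = integer(0),
                         end = integer(0), class = character(0),
                         stringsAsFactors = FALSE)), class = "sim_utrs"))
  }
  site_str <- function(class) {
    s <- site_strings(seed)
    switch(class,
           "8mer" = paste0(s$core7, "A"),
           "7mer-m8" = s$core7,
           "7mer-A1" = paste0(s$core6, "A"))
  }
  with_seed(rng_seed, {
    utrs <- character(n)
    truth <- list()
    for (i in seq_len(n)) {
      want <- if (is.null(planted_sites)) {
        planted_sites
      } else {
        planted_sites[planted_sites$utr == i, , drop = FALSE]
      }
      wanted_key <- if (is.null(want) || nrow(want) == 0L) {
        character(0)
      } else {
        site_len <- ifelse(want$class == "8mer", 8L, 7L)
        if (any(want$pos + site_len > utr_length[i])) {
          stop(sprintf("planted site exceeds UTR %d length", i),
               call. = FALSE)
        }
        paste(want$pos, want$class)
      }
      ok <- FALSE
      for (attempt in 1:200) {
        u <- paste(sample(DNA_BASES, utr_length[i], replace = TRUE),
                   collapse = "")
        if (length(wanted_key) > 0L) {
          for (k in seq_len(nrow(want))) {
            s <- site_str(want$class[k])
            substr(u, want$pos[k] + 1L, want$pos[k] + nchar(s)) <- s
          }
        }
        found <- scan_utr(u, seed)
        found_key <- paste(found$start, found$class)
        if (setequal(found_key, wanted_key) &&
            length(found_key) == length(wanted_key)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("could not realize requested sites in UTR %d", i),
             call. = FALSE)
      }
      utrs[i] <- u
      if (length(wanted_key) > 0L) {
        site_len <- ifelse(want$class == "8mer", 8L, 7L)
        truth[[length(truth) + 1L]] <-
          data.frame(utr_id = ids[i], start = want$pos,
                     end = want$pos + site_len, class = want$class,
                     stringsAsFactors = FALSE)
      }
    }
    names(utrs) <- ids
    truth <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(utr_id = character(0), start = integer(0),
                 end = integer(0), class = character(0),
                 stringsAsFactors = FALSE)
    }
    structure(list(utrs = utrs, truth = truth), class = "sim_utrs")
  })
}
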