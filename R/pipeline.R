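# Pipeline driver: runs the synthetic -> preprocess -> annotate ->
# anticorrelation -> enrichment -> intersection stages in dependency
# order against a single configuration, writing all results plus a
# provenance block to an output directory.

#' Pipeline configuration
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "preprocess", "annotate", "anticorr", "enrich",
#'   "intersect")`. Stages consume the outputs of earlier stages, which
#'   must either be selected too or already exist in `out_dir`.
#' @param sim A [sim_config()].
#' @param preprocess A [preprocess_params()].
#' @param anticorr An [anticorr_config()].
#' @param sponge A [sponge_params()].
#' @param mature Named character vector of mature miRNA sequences used
#'   for read simulation/annotation (default: a single miR-29-family
#'   mature sequence).
#' @param type_counts,extra_nonoverlap Passed to
#'   [simulate_deg_tables()] for the intersect stage.
#' @param alpha Consensus significance level.
#' @param fdr DEG filter threshold.
#' @param max_mm Annotation mismatch limit.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "preprocess", "annotate",
                                       "anticorr", "enrich", "intersect"),
                            sim = sim_config(),
                            preprocess = preprocess_params(),
                            anticorr = anticorr_config(
                              rng_seed = sim$rng_seed),
                            sponge = sponge_params(),
                            mature = c(mir29a = "TAGCACCATTTGAAATCGGTTA"),
                            type_counts = c(225L, 34L, 231L, 34L),
                            extra_nonoverlap = c(50L, 50L),
                            alpha = 0.05, fdr = 0.05, max_mm = 2L) {
  known <- c("simulate", "preprocess", "annotate", "anticorr", "enrich",
             "intersect")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known),
                                     collapse = ", "), call. = FALSE)
  }
  structure(list(stages = known[known %in% stages], sim = sim,
                 preprocess = preprocess, anticorr = anticorr,
                 sponge = sponge, mature = mature,
                 type_counts = as.integer(type_counts),
                 extra_nonoverlap = as.integer(extra_nonoverlap),
                 alpha = alpha, fdr = fdr, max_mm = as.integer(max_mm)),
            class = "pipeline_config")
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the selected stages in dependency order, writing per-stage
#' result files under `out_dir` together with `provenance.json` (package
#' version, configuration hash, seed). Reruns with an identical
#' configuration produce identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  log_stage <- function(stage, what, n) {
    message(sprintf("[%s] %s: %d records", stage, what, n))
  }
  emit <- function(name, writer, obj) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    written[[name]] <<- path
    path
  }
  if (!length(config$stages)) return(invisible(written))

  sim_expr <- NULL
  sim_reads <- NULL

  if ("simulate" %in% config$stages) {
    sim_expr <- simulate_expression(config$sim)
    emit("expression.tsv", write_tsv_matrix, sim_expr$expr)
    emit("samples.tsv", function(o, p) {
      utils::write.table(o, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }, sim_expr$samples)
    emit("mirna.tsv", function(o, p) {
      utils::write.table(
        data.frame(sample_id = names(o), expression = as.numeric(o)),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, sim_expr$mirna)
    emit("ground_truth.json", write_json_results,
         list(target_gene_ids = sim_expr$truth$target_gene_ids))
    sim_reads <- simulate_smallrna_reads(config$mature, config$sim)
    emit("reads.fastq", function(o, p) write_fastq(o, p), sim_reads$reads)
    log_stage("simulate", "genes", nrow(sim_expr$expr))
    log_stage("simulate", "reads", nrow(sim_reads$reads))
  }

  reads_pre <- NULL
  if ("preprocess" %in% config$stages) {
    raw <- if (!is.null(sim_reads)) {
      sim_reads$reads
    } else {
      read_fastq(file.path(out_dir, "reads.fastq"))
    }
    pp <- preprocess_reads(raw, config$preprocess)
    reads_pre <- pp$reads
    emit("reads.preprocessed.fastq", function(o, p) write_fastq(o, p),
         reads_pre)
    emit("preprocess_stats.json", write_json_results, pp$stats)
    log_stage("preprocess", "reads kept", nrow(reads_pre))
  }

  if ("annotate" %in% config$stages) {
    if (is.null(reads_pre)) {
      reads_pre <- read_fastq(file.path(out_dir,
                                        "reads.preprocessed.fastq"))
    }
    ann <- annotate_reads(reads_pre, config$mature, config$max_mm)
    emit("assignments.tsv", function(o, p) {
      utils::write.table(o, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }, ann$assignments)
    emit("counts.tsv", function(o, p) {
      utils::write.table(
        rbind(data.frame(mirna_id = names(o), count = as.integer(o)),
              data.frame(mirna_id = "*unassigned*",
                         count = ann$unassigned)),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, ann$counts)
    log_stage("annotate", "assigned reads", nrow(ann$assignments))
  }

  if ("anticorr" %in% config$stages || "enrich" %in% config$stages) {
    if (is.null(sim_expr)) {
      expr <- read_tsv_matrix(file.path(out_dir, "expression.tsv"))
      mir_df <- utils::read.delim(file.path(out_dir, "mirna.tsv"))
      mirna <- stats::setNames(mir_df$expression, mir_df$sample_id)
      truth <- jsonlite::read_json(file.path(out_dir,
                                             "ground_truth.json"),
                                   simplifyVector = TRUE)
      targets <- truth$target_gene_ids
      samples <- utils::read.delim(file.path(out_dir, "samples.tsv"))
    } else {
      expr <- sim_expr$expr
      mirna <- sim_expr$mirna
      targets <- sim_expr$truth$target_gene_ids
      samples <- sim_expr$samples
    }
  }

  if ("anticorr" %in% config$stages) {
    res <- anticorr_test(expr, mirna, targets, config$anticorr, samples)
    emit("anticorr.json", write_json_results,
         list(D = res$D, p = res$p, n_targets = length(res$r_t),
              n_null = length(res$r_0),
              median_target_r = stats::median(res$r_t),
              median_null_r = stats::median(res$r_0)))
    log_stage("anticorr", "target correlations", length(res$r_t))
  }

  if ("enrich" %in% config$stages) {
    # cluster = age-declining genes (negative correlation with age)
    age_r <- as.numeric(stats::cor(t(expr), samples$age_weeks))
    cluster <- rownames(expr)[age_r < -0.3]
    et <- enrichment_tests(cluster, intersect(targets, rownames(expr)),
                           rownames(expr))
    rec <- consensus_enrichment(
      data.frame(mirna_id = names(config$mature)[1],
                 p_binomial = et$p_binomial, p_fisher = et$p_fisher,
                 p_hypergeometric = et$p_hypergeometric),
      config$alpha)
    emit("enrichment.json", write_json_results,
         list(counts = as.list(et$counts), records = rec))
    log_stage("enrich", "cluster genes", length(cluster))
  }

  if ("intersect" %in% config$stages) {
    degs <- simulate_deg_tables(config$type_counts,
                                config$extra_nonoverlap, config$sim)
    emit("deg_aging.tsv", write_deg_table, degs$aging)
    emit("deg_sponge.tsv", write_deg_table, degs$sponge)
    typed <- classify_types(degs$aging, degs$sponge)
    conc <- concordance(typed)
    emit("concordance.json", write_json_results,
         list(counts = as.list(conc$counts), total = conc$total,
              concordant = conc$concordant,
              concordant_percent = conc$concordant_percent,
              discordant_percent = conc$discordant_percent,
              p = conc$p, test_used = conc$test_used,
              foldchange_r = foldchange_correlation(degs$aging,
                                                    degs$sponge)))
    log_stage("intersect", "typed genes", nrow(typed))
  }

  prov <- list(package = "miraging",
               version = as.character(utils::packageVersion("miraging")),
               config_hash = rlang::hash(unclass(config)),
               rng_seed = config$sim$rng_seed,
               stages = config$stages)
  emit("provenance.json", write_json_results, prov)
  invisible(written)
}
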