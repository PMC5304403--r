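# Shared readers/writers: FASTA (via Biostrings), FASTQ (plain 4-line
# Sanger/Phred+33 records, validated per record), TSV matrices and DEG
# tables, JSON results.

#' Read a FASTA file of DNA/RNA sequences
#'
#' RNA input is normalized to the DNA alphabet (U -> T); when that
#' happens the result carries attribute `u_converted = TRUE`. Ids are
#' the first whitespace-delimited token of each header and must be
#' unique.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id '%s' in %s",
                 ids[duplicated(ids)][1], path), call. = FALSE)
  }
  u <- any(grepl("U", seqs, fixed = TRUE))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    if (grepl("[^ACGTN]", seqs[i])) {
      stop(sprintf("non-ACGTN character in FASTA record '%s'", ids[i]),
           call. = FALSE)
    }
  }
  names(seqs) <- ids
  attr(seqs, "u_converted") <- u
  seqs
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a FASTQ file (Sanger/Phred+33)
#'
#' Expects plain 4-line records. Malformed records — missing '@'/'+'
#' markers or a sequence/quality length mismatch — raise an error naming
#' the offending record.
#'
#' @param path FASTQ file path (optionally gzipped).
#' @return A read set data.frame (id, seq, qual).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("FASTQ %s: line count not a multiple of 4", path),
         call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (n > 0L) {
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
    if (length(bad)) {
      stop(sprintf("FASTQ %s: malformed record near '%s'", path,
                   hdr[bad[1]]), call. = FALSE)
    }
    ids <- sub("\\s.*$", "", substring(hdr, 2L))
    bad <- which(nchar(seq) != nchar(qual))
    if (length(bad)) {
      stop(sprintf("FASTQ %s: sequence/quality length mismatch in '%s'",
                   path, ids[bad[1]]), call. = FALSE)
    }
  } else {
    ids <- character(0)
  }
  data.frame(id = ids, seq = toupper(seq), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write a read set to FASTQ
#'
#' @param reads data.frame with columns id, seq, qual.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a TSV expression matrix
#'
#' First column: gene id (must be unique); header row: sample ids; all
#' remaining cells numeric.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene id '%s' in %s", ids[duplicated(ids)][1],
                 path), call. = FALSE)
  }
  m <- df[, -1, drop = FALSE]
  for (j in seq_along(m)) {
    if (!is.numeric(m[[j]])) {
      bad <- ids[which(is.na(suppressWarnings(as.numeric(m[[j]]))))[1]]
      stop(sprintf("non-numeric cell in column '%s' (gene '%s') of %s",
                   names(m)[j], bad, path), call. = FALSE)
    }
  }
  m <- as.matrix(m)
  rownames(m) <- ids
  m
}

#' Write a matrix as TSV (gene id first column)
#'
#' @param m Matrix with rownames and colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DEG table (gene_id, log2FC, PValue, FDR)
#'
#' @param path TSV path.
#' @return data.frame with the four validated columns.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2FC", "PValue", "FDR")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(df$log2FC))) {
    stop(sprintf("non-finite log2FC in %s (gene '%s')", path,
                 df$gene_id[!is.finite(df$log2FC)][1]), call. = FALSE)
  }
  if (any(df$FDR < 0 | df$FDR > 1)) {
    stop(sprintf("FDR outside [0,1] in %s", path), call. = FALSE)
  }
  df[, need]
}

#' Write a DEG table as TSV
#' @param df DEG data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set file (one id per line)
#' @param path Text file path.
#' @return Character vector of ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write results as JSON
#'
#' @param x A (possibly nested) list of results.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_json_results <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
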