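# Small RNA-seq preprocessing and two-phase annotation against a mature
# miRNA reference. Phase 1 places each (short) read inside a mature
# sequence; reads longer than every compatible reference are rescued in
# phase 2 by placing mature sequences inside the read — the standard
# short-read aligner cannot annotate such 3'-extended isomiR reads.

#' Preprocessing parameters for small RNA-seq reads
#'
#' @param adapter 3' adapter sequence (ACGT).
#' @param max_adapter_mismatches Maximum mismatches tolerated in a
#'   full-length adapter overlap; shorter overlaps get a prorated budget
#'   of `min(max_adapter_mismatches, floor(L/8))` mismatches for an
#'   overlap of L nt, and overlaps shorter than `min_overlap` are never
#'   trimmed.
#' @param min_len,max_len Post-trimming length bounds (nt), inclusive.
#' @param min_overlap Minimum adapter overlap (nt) required to trim.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                              max_adapter_mismatches = 2L,
                              min_len = 18L, max_len = 33L,
                              min_overlap = 6L) {
  check_dna(adapter, "adapter")
  stopifnot(min_len <= max_len, max_adapter_mismatches >= 0L,
            min_overlap >= 1L)
  structure(list(adapter = adapter,
                 max_adapter_mismatches = as.integer(max_adapter_mismatches),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_overlap = as.integer(min_overlap)),
            class = "preprocess_params")
}

#' Construct a read set
#'
#' @param id,seq,qual Character vectors of equal length; `qual` must
#'   match `seq` in per-record length.
#' @return data.frame with columns id, seq, qual.
#' @export
read_set <- function(id, seq, qual = strrep("I", nchar(seq))) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("sequence/quality length mismatch in record '%s'", id[bad[1]]),
         call. = FALSE)
  }
  data.frame(id = as.character(id), seq = toupper(as.character(seq)),
             qual = as.character(qual), stringsAsFactors = FALSE)
}

#' Remove reads containing an 'N'
#'
#' @param reads A read set (data.frame id, seq, qual).
#' @return The read set restricted to N-free reads, input order preserved.
#' @export
filter_n <- function(reads) {
  reads[!grepl("N", reads$seq, fixed = TRUE), , drop = FALSE]
}

# Single left-to-right pass: earliest read position whose remaining
# sequence matches a prefix of the adapter within the prorated mismatch
# budget. Returns the new read length (0-based trim point).
trim_point <- function(seq_i, ad_i, max_mm, min_overlap) {
  n <- length(seq_i)
  m <- length(ad_i)
  if (n < min_overlap) return(n)
  for (s in seq_len(n - min_overlap + 1L)) {
    L <- min(n - s + 1L, m)
    budget <- min(max_mm, L %/% 8L)
    if (sum(seq_i[s:(s + L - 1L)] != ad_i[seq_len(L)]) <= budget) {
      return(s - 1L)
    }
  }
  n
}

#' Trim the 3' adapter from reads
#'
#' Finds the longest 3' portion of each read that aligns to a prefix of
#' the adapter within the prorated mismatch budget (see
#' [preprocess_params()]) and removes it together with everything 3' of
#' it; qualities are trimmed in lockstep. The scan is iterated to a fixed
#' point, so trimming is idempotent. Reads without an adapter signal are
#' returned unchanged.
#'
#' @param reads A read set.
#' @param params A [preprocess_params()].
#' @return The trimmed read set.
#' @export
trim_adapter <- function(reads, params = preprocess_params()) {
  ad_i <- seq_ints(params$adapter)
  for (i in seq_len(nrow(reads))) {
    repeat {
      si <- seq_ints(reads$seq[i])
      tp <- trim_point(si, ad_i, params$max_adapter_mismatches,
                       params$min_overlap)
      if (tp == length(si)) break
      reads$seq[i] <- substr(reads$seq[i], 1L, tp)
      reads$qual[i] <- substr(reads$qual[i], 1L, tp)
      if (tp == 0L) break
    }
  }
  reads
}

#' Retain reads within the annotatable length window
#'
#' @param reads A (trimmed) read set.
#' @param params A [preprocess_params()]; defaults keep 18-33 nt.
#' @return The filtered read set.
#' @export
filter_length <- function(reads, params = preprocess_params()) {
  len <- nchar(reads$seq)
  reads[len >= params$min_len & len <= params$max_len, , drop = FALSE]
}

#' Full preprocessing: N filter, adapter trim, length filter
#'
#' @inheritParams trim_adapter
#' @return A list: `reads` (preprocessed read set) and `stats` (record
#'   counts after each step).
#' @export
preprocess_reads <- function(reads, params = preprocess_params()) {
  n0 <- nrow(reads)
  reads <- filter_n(reads)
  n1 <- nrow(reads)
  reads <- trim_adapter(reads, params)
  reads <- filter_length(reads, params)
  list(reads = reads,
       stats = list(input = n0, after_n_filter = n1,
                    after_length_filter = nrow(reads)))
}

#' Load a mature miRNA reference
#'
#' Normalizes U to T, validates the alphabet and id uniqueness.
#'
#' @param x Named character vector of mature sequences, or a FASTA path.
#' @return Named character vector (ACGT) of class `mature_reference`.
#' @export
mature_reference <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- read_fasta(x)
  }
  if (length(x) == 0L) stop("empty mature reference", call. = FALSE)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("mature reference ids must be unique and non-empty", call. = FALSE)
  }
  x <- vapply(x, normalize_dna, character(1))
  for (i in seq_along(x)) check_dna(x[[i]], names(x)[i])
  structure(x, class = c("mature_reference", "character"))
}

# Best ungapped sense-strand placement of the shorter sequence inside the
# longer, enumerated over references and offsets. Ties: fewest
# mismatches, then smallest offset, then reference file order; any
# residual tie at the minimal mismatch count is flagged.
best_placement <- function(read_i, ref_ints, mode = c("read_in_ref",
                                                      "ref_in_read"),
                           max_mm = 2L) {
  mode <- match.arg(mode)
  best <- NULL
  n_best <- 0L
  lr <- length(read_i)
  for (j in seq_along(ref_ints)) {
    ri <- ref_ints[[j]]
    if (mode == "read_in_ref") {
      if (lr > length(ri)) next
      max_off <- length(ri) - lr
    } else {
      if (length(ri) >= lr) next
      max_off <- lr - length(ri)
    }
    for (o in 0:max_off) {
      mm <- if (mode == "read_in_ref") {
        sum(read_i != ri[(o + 1L):(o + lr)])
      } else {
        sum(ri != read_i[(o + 1L):(o + length(ri))])
      }
      if (mm > max_mm) next
      if (is.null(best) || mm < best$mismatches) {
        best <- list(ref = j, mismatches = mm, offset = o)
        n_best <- 1L
      } else if (mm == best$mismatches) {
        n_best <- n_best + 1L
        # same mismatch count: prefer the smaller offset, then file order
        if (o < best$offset) best <- list(ref = j, mismatches = mm,
                                          offset = o)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$tie <- n_best > 1L
  best
}

#' Phase-1 alignment: place a read inside a mature sequence
#'
#' Enumerates every sense-strand, ungapped placement of the whole read
#' inside each reference at least as long as the read, and returns the
#' assignment with the fewest mismatches (ties: smallest offset, then
#' reference order; ties are flagged).
#'
#' @param read A single-row read set or a list with `id` and `seq`.
#' @param ref A [mature_reference()].
#' @param max_mm Maximum mismatches (default 2).
#' @return A one-row data.frame (read_id, mirna_id, phase, mismatches,
#'   offset, tie) or NULL when no placement is within `max_mm`.
#' @export
align_phase1 <- function(read, ref, max_mm = 2L) {
  align_one(read, ref, max_mm, phase = 1L)
}

#' Phase-2 alignment: place a mature sequence inside a long read
#'
#' For reads strictly longer than a reference, enumerates every
#' sense-strand, ungapped placement of the whole mature sequence inside
#' the read. Used only for reads phase 1 could not assign.
#'
#' @inheritParams align_phase1
#' @return As [align_phase1()], with `phase = 2`; NULL when unassigned.
#' @export
align_phase2 <- function(read, ref, max_mm = 2L) {
  align_one(read, ref, max_mm, phase = 2L)
}

align_one <- function(read, ref, max_mm, phase) {
  seq <- if (is.data.frame(read)) read$seq[1] else read$seq
  id <- if (is.data.frame(read)) read$id[1] else read$id
  if (grepl("N", seq, fixed = TRUE)) {
    stop(sprintf("read '%s' contains N after preprocessing", id),
         call. = FALSE)
  }
  ref_ints <- lapply(unclass(ref), seq_ints)
  b <- best_placement(seq_ints(seq), ref_ints,
                      if (phase == 1L) "read_in_ref" else "ref_in_read",
                      max_mm)
  if (is.null(b)) return(NULL)
  data.frame(read_id = id, mirna_id = names(ref)[b$ref], phase = phase,
             mismatches = b$mismatches, offset = b$offset, tie = b$tie,
             stringsAsFactors = FALSE)
}

#' Two-phase annotation and quantification of preprocessed reads
#'
#' Each read is first aligned inside the mature reference (phase 1);
#' reads that fail — typically 3'-extended isomiRs longer than every
#' mature sequence — get a second chance with the mature sequences
#' aligned inside the read (phase 2). Counts are tallied per miRNA;
#' assigned plus unassigned always equals the number of input reads.
#'
#' @param reads A preprocessed read set (no Ns).
#' @param ref A [mature_reference()] (or named character vector).
#' @param max_mm Maximum mismatches per placement (default 2).
#' @return A list of class `annotation`: `assignments` (data.frame
#'   read_id, mirna_id, phase, mismatches, offset, tie), `counts` (named
#'   integer vector over all reference ids), `unassigned` (integer), and
#'   `n_ambiguous` (reads whose best placement was tied).
#' @export
annotate_reads <- function(reads, ref, max_mm = 2L) {
  ref <- mature_reference(ref)
  if (any(grepl("N", reads$seq, fixed = TRUE))) {
    bad <- reads$id[grepl("N", reads$seq, fixed = TRUE)][1]
    stop(sprintf("read '%s' contains N after preprocessing", bad),
         call. = FALSE)
  }
  ref_ints <- lapply(unclass(ref), seq_ints)
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    ri <- seq_ints(reads$seq[i])
    b <- best_placement(ri, ref_ints, "read_in_ref", max_mm)
    phase <- 1L
    if (is.null(b)) {
      b <- best_placement(ri, ref_ints, "ref_in_read", max_mm)
      phase <- 2L
    }
    if (!is.null(b)) {
      rows[[i]] <- data.frame(read_id = reads$id[i],
                              mirna_id = names(ref)[b$ref], phase = phase,
                              mismatches = b$mismatches, offset = b$offset,
                              tie = b$tie, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  assignments <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (is.null(assignments)) {
    assignments <- data.frame(read_id = character(0), mirna_id = character(0),
                              phase = integer(0), mismatches = integer(0),
                              offset = integer(0), tie = logical(0),
                              stringsAsFactors = FALSE)
  }
  counts <- stats::setNames(integer(length(ref)), names(ref))
  tab <- table(assignments$mirna_id)
  counts[names(tab)] <- as.integer(tab)
  n_amb <- sum(assignments$tie)
  if (n_amb > 0L) {
    message(sprintf("%d read(s) had tied best placements; first hit kept",
                    n_amb))
  }
  structure(list(assignments = assignments, counts = counts,
                 unassigned = nrow(reads) - nrow(assignments),
                 n_ambiguous = n_amb),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("Two-phase small-RNA annotation\n")
  cat(sprintf("  assigned: %d (phase 1: %d, phase 2: %d), unassigned: %d\n",
              nrow(x$assignments), sum(x$assignments$phase == 1L),
              sum(x$assignments$phase == 2L), x$unassigned))
  invisible(x)
}
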