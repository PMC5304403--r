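# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded simulation
#' functions do not disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string (character scalar)
#' @noRd
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Watson-Crick complement, vectorized over single bases
#' @noRd
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Transversion of a base: A<->C, G<->T. Deterministic substitution used to
# break complementarity in sponge bulges and site mutagenesis.
transversion <- function(b) chartr("ACGT", "CATG", b)

#' Stop unless a scalar DNA string over the given alphabet
#' @noRd
check_dna <- function(x, name = deparse(substitute(x)), allow = "ACGT") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("'%s' must be a non-empty character scalar", name),
         call. = FALSE)
  }
  bad <- gsub(sprintf("[%s]", allow), "", x)
  if (nchar(bad) > 0L) {
    stop(sprintf("'%s' contains characters outside {%s}: '%s'",
                 name, paste(strsplit(allow, "")[[1]], collapse = ","),
                 substr(bad, 1L, 10L)), call. = FALSE)
  }
  invisible(x)
}

#' Normalize an RNA/DNA string to the DNA alphabet (U -> T, uppercase)
#' @noRd
normalize_dna <- function(x) toupper(chartr("uU", "tT", x))

#' Hamming mismatches between equal-length integer-encoded sequences
#' @noRd
mismatch_count <- function(a, b) sum(a != b)

#' utf8 integer encoding of a sequence string
#' @noRd
seq_ints <- function(x) utf8ToInt(x)
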