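# Canonical seed-site scanning on 3'-UTRs, binding-site mutagenesis, and
# bulged sponge (miRNA decoy) construct design.
#
# Site classes follow the canonical nomenclature: with the seed defined
# as miRNA positions 2-8 (5'->3'), a 7mer-m8 site is the exact reverse
# complement of positions 2-8; an 8mer extends it with an 'A' opposite
# miRNA position 1; a 7mer-A1 is the reverse complement of positions 2-7
# followed by that 'A'. No G:U wobble is allowed anywhere.

#' Define a miRNA seed
#'
#' @param mature Mature miRNA sequence (RNA or DNA; U is normalized to
#'   T), length >= 8.
#' @param seed_range 1-based inclusive positions of the seed (default
#'   2-8).
#' @return An object of class `seed_definition` with the normalized
#'   mature sequence and seed range.
#' @export
seed_definition <- function(mature, seed_range = c(2L, 8L)) {
  mature <- normalize_dna(mature)
  check_dna(mature, "mature")
  if (nchar(mature) < 8L) stop("mature sequence must be >= 8 nt",
                               call. = FALSE)
  stopifnot(length(seed_range) == 2L, seed_range[1] >= 1L,
            seed_range[2] <= nchar(mature), seed_range[1] < seed_range[2])
  structure(list(mature = mature, seed_range = as.integer(seed_range)),
            class = "seed_definition")
}

# UTR-side match strings for the seed: core7 = revcomp(m2..m8),
# core6 = revcomp(m2..m7).
site_strings <- function(seed) {
  a <- seed$seed_range[1]
  b <- seed$seed_range[2]
  list(core7 = revcomp(substr(seed$mature, a, b)),
       core6 = revcomp(substr(seed$mature, a, b - 1L)))
}

# all 0-based start positions of fixed pattern `pat` in `x`, overlapping
find_all <- function(x, pat) {
  hits <- gregexpr(paste0("(?=", pat, ")"), x, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Scan a 3'-UTR for canonical seed-match sites
#'
#' Reports every window matching the reverse complement of the seed:
#' 7mer-m8 matches are extended to 8mer when followed by an 'A'
#' (opposite miRNA position 1); 6mer cores followed by 'A' that are not
#' part of a 7mer-m8 match are reported as 7mer-A1. Overlapping sites
#' are all reported, sorted by start. 'N' never matches.
#'
#' @param utr UTR sequence (character scalar over A,C,G,T,N).
#' @param seed A [seed_definition()].
#' @return data.frame with 0-based half-open `start`, `end` and `class`
#'   in {"8mer", "7mer-m8", "7mer-A1"}; empty for UTRs shorter than 7 nt.
#' @export
scan_utr <- function(utr, seed) {
  utr <- toupper(utr)
  check_dna(utr, "utr", allow = "ACGTN")
  empty <- data.frame(start = integer(0), end = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (nchar(utr) < 7L) return(empty)
  s <- site_strings(seed)
  n <- nchar(utr)
  pos7 <- find_all(utr, s$core7)
  out <- list()
  for (p in pos7) {
    if (p + 8L <= n && substr(utr, p + 8L, p + 8L) == "A") {
      out[[length(out) + 1L]] <- list(p, p + 8L, "8mer")
    } else {
      out[[length(out) + 1L]] <- list(p, p + 7L, "7mer-m8")
    }
  }
  # 7mer-A1: core6 + A that is not the tail of a core7 match (a core7
  # match always contains core6 one position downstream, which is the
  # same physical site, not an additional one) and does not coincide
  # with a core7 start
  pos6 <- find_all(utr, paste0(s$core6, "A"))
  for (p in setdiff(pos6, c(pos7, pos7 + 1L))) {
    out[[length(out) + 1L]] <- list(p, p + 7L, "7mer-A1")
  }
  if (!length(out)) return(empty)
  df <- data.frame(start = vapply(out, `[[`, integer(1), 1),
                   end = vapply(out, `[[`, integer(1), 2),
                   class = vapply(out, `[[`, character(1), 3),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Scan many UTRs
#'
#' @param utrs Named character vector of UTR sequences.
#' @inheritParams scan_utr
#' @return data.frame with columns utr_id, start, end, class.
#' @export
scan_utrs <- function(utrs, seed) {
  res <- lapply(seq_along(utrs), function(i) {
    df <- scan_utr(utrs[[i]], seed)
    if (nrow(df)) cbind(utr_id = names(utrs)[i], df,
                        stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(utr_id = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Mutate a seed site to abolish miRNA binding
#'
#' Substitutes `n_mut` positions inside the seed-pairing core of a
#' scanned site with transversions of the current base, breaking
#' Watson-Crick complementarity to the seed, and verifies by rescanning
#' that no site overlapping the original window remains (re-drawing the
#' mutated positions if a shifted match survives). Output length equals
#' input length and the Hamming distance to the input equals `n_mut`.
#'
#' @param utr UTR sequence.
#' @param site One row of [scan_utr()] output (list or data.frame row
#'   with start, end, class).
#' @param n_mut Number of substitutions (default 3).
#' @param seed A [seed_definition()] used for the verification rescan.
#' @param rng_seed Seed controlling which core positions are mutated.
#' @return The mutated UTR sequence.
#' @export
mutate_site <- function(utr, site, seed, n_mut = 3L, rng_seed = 1L) {
  utr <- toupper(utr)
  start <- as.integer(site$start)
  end <- as.integer(site$end)
  if (start < 0L || end > nchar(utr)) stop("site outside UTR",
                                           call. = FALSE)
  if (n_mut == 0L) return(utr)
  # seed-pairing core: the seed-complementary positions of the site
  # (excludes the 3' 'A' of 8mer/7mer-A1 sites, which pairs nothing)
  core_len <- if (site$class == "7mer-A1") 6L else 7L
  core <- start + seq_len(core_len) - 1L  # 0-based positions
  if (n_mut > core_len) stop("n_mut exceeds the seed-pairing core",
                             call. = FALSE)
  with_seed(rng_seed, {
    for (attempt in 1:50) {
      idx <- sort(sample(core, n_mut))
      ch <- strsplit(utr, "")[[1]]
      for (p in idx) ch[p + 1L] <- transversion(ch[p + 1L])
      mut <- paste(ch, collapse = "")
      hits <- scan_utr(mut, seed)
      if (!nrow(hits) || !any(hits$start < end & hits$end > start)) {
        return(mut)
      }
    }
    stop("could not abolish the site within 50 attempts", call. = FALSE)
  })
}

#' Sponge construct parameters
#'
#' @param repeats Number of tandem binding sites (default 7).
#' @param bulge miRNA positions left unpaired (central bulge); default
#'   9-12, i.e. immediately 3' of the seed.
#' @param spacer Spacer sequence between sites; if it creates a spurious
#'   seed site at a junction, alternatives from a fixed list are tried.
#' @return An object of class `sponge_params`.
#' @export
sponge_params <- function(repeats = 7L, bulge = 9:12, spacer = "CATT") {
  stopifnot(repeats >= 1L, length(bulge) == 4L,
            all(diff(bulge) == 1L))
  if (nchar(spacer) > 0L) check_dna(spacer, "spacer")
  structure(list(repeats = as.integer(repeats), bulge = as.integer(bulge),
                 spacer = spacer),
            class = "sponge_params")
}

#' Design a bulged miRNA sponge construct
#'
#' Builds `repeats` tandem binding sites, each the reverse complement of
#' the full mature sequence with the four positions pairing miRNA
#' nucleotides 9-12 substituted (deterministic transversions) so they
#' cannot pair — a central bulge immediately after the seed that favors
#' stable sequestration over Ago2-mediated slicing. Sites are joined by
#' the spacer; the finished construct is verified by rescanning to carry
#' exactly `repeats` seed sites at the recorded coordinates.
#'
#' @param seed A [seed_definition()] (mature length >= 12).
#' @param params A [sponge_params()].
#' @return A list of class `sponge_construct`: `sequence`, `sites`
#'   (data.frame with 0-based half-open site coordinates), and
#'   `pairing` (data.frame mirna_pos, site_pos, complementary).
#' @export
design_sponge <- function(seed, params = sponge_params()) {
  m <- seed$mature
  mlen <- nchar(m)
  if (mlen < 12L) stop("mature sequence must be >= 12 nt", call. = FALSE)
  site <- strsplit(revcomp(m), "")[[1]]
  mch <- strsplit(m, "")[[1]]
  # site index (1-based) pairing miRNA position k is mlen - k + 1
  for (k in params$bulge) {
    i <- mlen - k + 1L
    site[i] <- transversion(site[i])
  }
  site_seq <- paste(site, collapse = "")
  pairing <- data.frame(
    mirna_pos = seq_len(mlen),
    site_pos = mlen - seq_len(mlen),  # 0-based within the site
    complementary = vapply(seq_len(mlen), function(k) {
      site[mlen - k + 1L] == comp_base(mch[k])
    }, logical(1))
  )
  spacers <- unique(c(params$spacer, "CATT", "GTAA", "CAAT", "TTCA",
                      "ACCT", "TGGA"))
  for (sp in spacers) {
    construct <- paste(rep(site_seq, params$repeats),
                       collapse = sp)
    step <- mlen + nchar(sp)
    starts <- (seq_len(params$repeats) - 1L) * step
    sites <- data.frame(start = starts, end = starts + mlen)
    # expected seed-site starts within the construct: core7 sits at
    # site offset mlen - 8 (0-based)
    expected <- starts + (mlen - 8L)
    hits <- scan_utr(construct, seed)
    if (nrow(hits) == params$repeats &&
        all(sort(hits$start) == sort(expected))) {
      return(structure(list(sequence = construct, sites = sites,
                            pairing = pairing, spacer = sp,
                            repeats = params$repeats),
                       class = "sponge_construct"))
    }
  }
  stop(paste("could not design a construct with exactly one seed site per",
             "repeat; the mature sequence itself may contain internal seed",
             "matches"), call. = FALSE)
}

#' @export
print.sponge_construct <- function(x, ...) {
  cat(sprintf("miRNA sponge: %d bulged sites, spacer '%s', %d nt\n",
              x$repeats, x$spacer, nchar(x$sequence)))
  cat(x$sequence, "\n")
  invisible(x)
}
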