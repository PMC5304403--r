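# Independent brute-force oracles and fixture generators. These
# deliberately avoid the package's own code paths: naive loops,
# substring comparisons and direct formulas only.

BASES <- c("A", "C", "G", "T")

ocomp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reverse complement via explicit character lookup
orc <- function(x) {
  ch <- rev(strsplit(x, "")[[1]])
  paste(ocomp[ch], collapse = "")
}

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# sample one element of a vector (safe for length-1 vectors)
pick1 <- function(v) v[sample.int(length(v), 1)]

# substitute k random positions with a different base
substitute_bases <- function(x, k) {
  ch <- strsplit(x, "")[[1]]
  idx <- sample(seq_along(ch), k)
  for (i in idx) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

# textbook Pearson product-moment formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# max ECDF gap over every observed threshold
oracle_ks_D <- function(a, b) {
  gaps <- vapply(sort(unique(c(a, b))), function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1))
  max(gaps)
}

# Hochberg step-up executed literally: sort descending, find the largest
# i with p_(i) <= alpha/(m - i + 1) ... adjusted form via the minimum of
# scaled p-values from the top
oracle_hochberg <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (pos in seq_len(m)) {
    i <- o[pos]
    running <- min(running, (pos) * p[i])
    adj[i] <- min(running, 1)
  }
  adj
}

# exact hypergeometric upper tail by combinatorial summation
oracle_hyper_tail <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# mismatches between equal-length strings by character comparison
ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# Brute-force two-phase aligner: enumerate every placement of the whole
# read inside each reference (phase 1) else every placement of each
# reference inside the read (phase 2); ties resolved by mismatches,
# then offset, then reference order.
oracle_annotate <- function(reads, ref, max_mm = 2L) {
  ref_ids <- names(ref)
  out <- list()
  for (i in seq_len(nrow(reads))) {
    rd <- reads$seq[i]
    cand <- list()
    for (j in seq_along(ref)) {
      rf <- ref[[j]]
      if (nchar(rd) <= nchar(rf)) {
        for (o in 0:(nchar(rf) - nchar(rd))) {
          mm <- ham(rd, substr(rf, o + 1, o + nchar(rd)))
          if (mm <= max_mm) {
            cand[[length(cand) + 1]] <- c(j, mm, o, 1)
          }
        }
      }
    }
    if (!length(cand)) {
      for (j in seq_along(ref)) {
        rf <- ref[[j]]
        if (nchar(rf) < nchar(rd)) {
          for (o in 0:(nchar(rd) - nchar(rf))) {
            mm <- ham(rf, substr(rd, o + 1, o + nchar(rf)))
            if (mm <= max_mm) {
              cand[[length(cand) + 1]] <- c(j, mm, o, 2)
            }
          }
        }
      }
    }
    if (length(cand)) {
      tab <- do.call(rbind, cand)
      tab <- tab[order(tab[, 2], tab[, 3], tab[, 1]), , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        read_id = reads$id[i], mirna_id = ref_ids[tab[1, 1]],
        phase = as.integer(tab[1, 4]), mismatches = as.integer(tab[1, 2]),
        offset = as.integer(tab[1, 3]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(0), mirna_id = character(0),
                      phase = integer(0), mismatches = integer(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# random annotation instance: references plus a mix of derived
# (substituted / truncated / 3'-extended) and fully random reads
random_annot_instance <- function(max_reads = 100L, max_refs = 10L) {
  n_refs <- sample(1:max_refs, 1)
  ref <- character(n_refs)
  for (j in seq_len(n_refs)) ref[j] <- random_seq(sample(15:40, 1))
  names(ref) <- sprintf("mir%02d", seq_len(n_refs))
  n_reads <- sample(5:max_reads, 1)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    kind <- sample(c("sub", "trunc", "ext", "rand"), 1)
    src <- ref[[sample(n_refs, 1)]]
    seqs[i] <- switch(kind,
      sub = substitute_bases(src, sample(0:3, 1)),
      trunc = {
        len <- pick1(15:nchar(src))
        substitute_bases(substr(src, 1, len), sample(0:2, 1))
      },
      ext = {
        ext <- random_seq(sample(1:6, 1))
        substitute_bases(paste0(src, ext), sample(0:2, 1))
      },
      rand = random_seq(sample(15:40, 1)))
  }
  list(reads = read_set(sprintf("r%04d", seq_len(n_reads)), seqs),
       ref = ref)
}

# Brute-force seed-site scanner: compare every 7/8-nt window against
# independently built site strings.
oracle_scan <- function(utr, mature) {
  core7 <- orc(substr(mature, 2, 8))
  core6 <- orc(substr(mature, 2, 7))
  n <- nchar(utr)
  res <- list()
  pos7 <- integer(0)
  for (p in 0:(n - 7)) {
    if (substr(utr, p + 1, p + 7) == core7) pos7 <- c(pos7, p)
  }
  for (p in pos7) {
    if (p + 8 <= n && substr(utr, p + 8, p + 8) == "A") {
      res[[length(res) + 1]] <- data.frame(start = p, end = p + 8,
                                           class = "8mer")
    } else {
      res[[length(res) + 1]] <- data.frame(start = p, end = p + 7,
                                           class = "7mer-m8")
    }
  }
  if (n >= 7) {
    for (p in 0:(n - 7)) {
      if (substr(utr, p + 1, p + 7) == paste0(core6, "A") &&
          !(p %in% pos7) && !((p - 1) %in% pos7)) {
        res[[length(res) + 1]] <- data.frame(start = p, end = p + 7,
                                             class = "7mer-A1")
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df$class <- as.character(df$class)
  df
}

# Brute-force adapter trimmer mirroring the definition: repeatedly
# remove the longest 3' stretch matching an adapter prefix within the
# prorated budget, until stable.
oracle_trim <- function(seq, adapter, max_mm = 2L, min_overlap = 6L) {
  repeat {
    n <- nchar(seq)
    cut <- n
    if (n >= min_overlap) {
      for (s in 1:(n - min_overlap + 1)) {
        L <- min(n - s + 1, nchar(adapter))
        if (ham(substr(seq, s, s + L - 1), substr(adapter, 1, L)) <=
            min(max_mm, L %/% 8)) {
          cut <- s - 1
          break
        }
      }
    }
    if (cut == n) return(seq)
    seq <- substr(seq, 1, cut)
    if (nchar(seq) == 0) return(seq)
  }
}

# a mature miRNA sequence usable for sponge design (no internal repeat
# of its own seed complement); mirrors real mature sequences
random_clean_mature <- function(len = 22) {
  repeat {
    m <- random_seq(len)
    core <- orc(substr(m, 2, 8))
    hits <- gregexpr(paste0("(?=", core, ")"), orc(m), perl = TRUE)[[1]]
    n_hits <- if (hits[1] == -1) 0 else length(hits)
    if (n_hits == 1) return(m)
  }
}

MIR29A <- "TAGCACCATTTGAAATCGGTTA"
ADAPTER <- "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC"
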