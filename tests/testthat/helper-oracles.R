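# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive results through a different route than the package
# code paths they check.

# quadratic-DP Smith-Waterman score (affine gaps: a gap of length g costs
# open + g * ext), one orientation
oracle_sw_score <- function(q, s, match = 1, mismatch = -2, open = 5,
                            ext = 2) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  m <- length(qc); n <- length(sc)
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)
  F <- matrix(-Inf, m + 1L, n + 1L)
  best <- 0
  for (i in 2:(m + 1L)) {
    for (j in 2:(n + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      sub <- if (qc[i - 1L] == sc[j - 1L]) match else mismatch
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

oracle_sw_best <- function(q, s, ...) {
  max(oracle_sw_score(q, s, ...), oracle_sw_score(revcomp(q), s, ...))
}

# seed-site scan oracle: vectorised substring comparison over every start of
# the circular scan string, most specific type per start
oracle_seed_sites <- function(seq_rna, mature, include_6mer = FALSE) {
  seed <- substr(mature, 2L, 8L)
  S <- chartr("Tt", "Uu", revcomp(chartr("Uu", "Tt", seed)))
  pats <- c(`8mer` = paste0(S, "A"), `7mer-m8` = S,
            `7mer-A1` = paste0(substr(S, 2L, 7L), "A"),
            `6mer` = substr(S, 2L, 7L))
  L <- nchar(seq_rna)
  scan <- paste0(seq_rna, substr(seq_rna, 1L, min(7L, L)))
  p <- seq_len(L)
  tp <- rep(NA_character_, L)
  tp[substring(scan, p, p + 5L) == pats[["6mer"]]] <- "6mer"
  tp[substring(scan, p, p + 6L) == pats[["7mer-A1"]]] <- "7mer-A1"
  tp[substring(scan, p, p + 6L) == pats[["7mer-m8"]]] <- "7mer-m8"
  tp[substring(scan, p, p + 7L) == pats[["8mer"]]] <- "8mer"
  keep_types <- c("8mer", "7mer-m8", "7mer-A1", if (include_6mer) "6mer")
  keep <- which(tp %in% keep_types)
  data.frame(start = keep - 1L, type = tp[keep], stringsAsFactors = FALSE)
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# venn-region counts by per-element membership enumeration
oracle_regions <- function(keys) {
  universe <- unique(unlist(keys, use.names = FALSE))
  pat <- vapply(universe, function(el)
    paste(as.integer(vapply(keys, function(k) el %in% k, logical(1))),
          collapse = ""), character(1))
  table(pat)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
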