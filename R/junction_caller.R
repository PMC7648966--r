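# Anchor-based back-splice junction detection.
#
# Reads that fail contiguous (linear) alignment have their terminal k-mers
# ("anchors") placed on the genome. If both anchors place uniquely on one
# chromosome and strand, in reversed orientation (the read's leading anchor
# downstream of its trailing anchor), the two anchor alignments are extended
# toward the read interior until the whole read is explained by two genomic
# segments whose joint breakpoint is flanked by the canonical splice signal
# (AG upstream of the acceptor, GT downstream of the donor, on the
# transcribed strand; CT..AC on the genomic plus strand for minus calls).

#' Build an exact k-mer anchor index over both strands
#'
#' A k-mer is "unique" iff it has exactly one occurrence over both strands;
#' N-containing k-mers are skipped.
#'
#' @param genome a [genome_bundle()].
#' @param k anchor length (>= 4; 20 in the published procedure).
#' @return an object of class `anchor_index`.
#' @export
build_anchor_index <- function(genome, k = 20L) {
  k <- as.integer(k)
  if (k < 4L) stopf("anchor length k must be >= 4")
  if (any(nchar(genome$sequences) < k))
    stopf("k = %d exceeds the shortest chromosome", k)
  pieces <- list()
  for (chrom in names(genome$sequences)) {
    s <- genome$sequences[[chrom]]
    n <- nchar(s) - k + 1L
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    pos <- seq_len(n)[ok] - 1L
    kmers <- kmers[ok]
    pieces[[length(pieces) + 1L]] <-
      data.table::data.table(kmer = kmers, chrom = chrom, pos = pos,
                             strand = "+")
    pieces[[length(pieces) + 1L]] <-
      data.table::data.table(kmer = revcomp(kmers), chrom = chrom, pos = pos,
                             strand = "-")
  }
  dt <- data.table::rbindlist(pieces)
  data.table::setkey(dt, kmer)
  structure(list(dt = dt, k = k), class = "anchor_index")
}

#' @export
print.anchor_index <- function(x, ...) {
  cat(sprintf("<anchor_index> k = %d, %s occurrence(s)\n", x$k,
              format(nrow(x$dt), big.mark = ",")))
  invisible(x)
}

#' Look up anchor occurrences
#'
#' @param index an [build_anchor_index()] result.
#' @param kmers character vector of k-mers.
#' @return data.table with columns `kmer`, `chrom`, `pos`, `strand`
#'   (0 rows for absent k-mers).
#' @export
anchor_lookup <- function(index, kmers) {
  res <- index$dt[data.table::data.table(kmer = kmers), nomatch = NULL,
                  on = "kmer"]
  res[]
}

# reference set for the toy linear aligner: chromosomes plus per-gene spliced
# transcript sequences (reads from spliced linear RNA must count as mapped)
linear_references <- function(genome) {
  cdna <- vapply(genome$genes, gene_cdna, character(1),
                 sequences = genome$sequences)
  refs <- c(genome$sequences, cdna)
  Biostrings::DNAStringSet(c(refs, setNames(revcomp(refs),
                                            paste0(names(refs), "_rc"))))
}

#' Toy contiguous aligner: split reads into mapped and unmapped
#'
#' A read is "mapped" iff its full length matches a chromosome or an
#' annotated spliced transcript contiguously with at most `mm` mismatches
#' (either orientation). With `mm > 0` the match is seeded by an exact
#' terminal k-mer (either end), so at most one read end may carry errors.
#' Reads shorter than `2 * k` are skipped with a warning.
#'
#' @param reads named character vector of read sequences (one sample).
#' @param index an `anchor_index` built on the same genome (supplies `k`).
#' @param genome the [genome_bundle()].
#' @param mm maximum mismatches (default 0 = exact).
#' @return list with `mapped_count`, `unmapped` (named character vector),
#'   and `skipped` (ids of too-short reads).
#' @export
align_linear <- function(reads, index, genome, mm = 0L) {
  k <- index$k
  widths <- nchar(reads)
  short <- widths < 2L * k
  if (any(short))
    warnf("%d read(s) shorter than 2k = %d skipped", sum(short), 2L * k)
  skipped <- names(reads)[short]
  reads <- reads[!short]
  widths <- widths[!short]
  if (!length(reads))
    return(list(mapped_count = 0L, unmapped = reads, skipped = skipped))

  refs <- linear_references(genome)
  mapped <- logical(length(reads))
  for (w in unique(widths)) {
    sel <- which(widths == w)
    x <- Biostrings::DNAStringSet(reads[sel])
    if (mm == 0L) {
      pd <- Biostrings::PDict(x)
      cnt <- Biostrings::vcountPDict(pd, refs, collapse = 1L)
      mapped[sel] <- cnt > 0L
    } else {
      hit <- rep(FALSE, length(sel))
      for (tb_start in c(1L, w - k + 1L)) {
        pd <- Biostrings::PDict(x, tb.start = tb_start, tb.width = k)
        cnt <- Biostrings::vcountPDict(pd, refs, max.mismatch = mm,
                                       collapse = 1L)
        hit <- hit | cnt > 0L
      }
      mapped[sel] <- hit
    }
  }
  list(mapped_count = sum(mapped), unmapped = reads[!mapped],
       skipped = skipped)
}

#' Call back-splice junction candidates from unmapped reads
#'
#' Implements anchor placement, the reversed-orientation test, breakpoint
#' extension and the canonical splice-signal requirement (see the file
#' header). Among signal-consistent breakpoints the one maximising the
#' acceptor-segment length is taken. Reads with non-unique or inconsistent
#' anchors, no signal-consistent breakpoint, or anchors in forward
#' orientation are dropped; drop reasons are tallied in the `log` attribute.
#'
#' @param reads named character vector of unmapped reads.
#' @param index `anchor_index` over the genome.
#' @param genome the [genome_bundle()].
#' @param mm mismatches allowed in the extension (anchors stay exact).
#' @param require_splice_signal if `FALSE`, the GT/AG requirement is dropped
#'   (ablation mode) and the breakpoint with the longest acceptor segment is
#'   reported.
#' @return data.frame of candidate calls (`read_id`, `chrom`, `start`,
#'   `end`, `strand`, `read_seq`) with a `log` attribute of drop counters.
#' @export
call_backsplice <- function(reads, index, genome, mm = 0L,
                            require_splice_signal = TRUE) {
  k <- index$k
  log <- c(too_short = 0L, anchor_missing = 0L, anchor_nonunique = 0L,
           cross_chrom_or_strand = 0L, forward_orientation = 0L,
           no_breakpoint = 0L, called = 0L)
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), read_seq = character(0),
                      stringsAsFactors = FALSE)
  if (!length(reads)) {
    attr(empty, "log") <- log
    return(empty)
  }
  w <- nchar(reads)
  ok <- w >= 2L * k
  log[["too_short"]] <- sum(!ok)
  reads <- reads[ok]
  w <- w[ok]

  a1 <- substr(reads, 1L, k)
  a2 <- substr(reads, w - k + 1L, w)
  occ <- anchor_lookup(index, unique(c(a1, a2)))
  occ_n <- occ[, list(n = .N), by = "kmer"]
  n_of <- setNames(occ_n$n, occ_n$kmer)
  n1 <- n_of[a1]; n1[is.na(n1)] <- 0L
  n2 <- n_of[a2]; n2[is.na(n2)] <- 0L
  log[["anchor_missing"]] <- sum(n1 == 0L | n2 == 0L)
  log[["anchor_nonunique"]] <- sum(n1 > 0L & n2 > 0L & (n1 > 1L | n2 > 1L))
  sel <- which(n1 == 1L & n2 == 1L)

  uocc <- occ[occ$kmer %in% names(n_of)[n_of == 1L], ]
  o_chrom <- setNames(uocc$chrom, uocc$kmer)
  o_pos <- setNames(uocc$pos, uocc$kmer)
  o_strand <- setNames(uocc$strand, uocc$kmer)

  out <- vector("list", length(sel))
  for (ii in seq_along(sel)) {
    i <- sel[ii]
    c1 <- o_chrom[[a1[i]]]; c2 <- o_chrom[[a2[i]]]
    s1 <- o_strand[[a1[i]]]; s2 <- o_strand[[a2[i]]]
    if (c1 != c2 || s1 != s2) {
      log[["cross_chrom_or_strand"]] <- log[["cross_chrom_or_strand"]] + 1L
      next
    }
    L <- w[i]
    if (s1 == "+") {
      Q <- reads[[i]]
      firstpos <- o_pos[[a1[i]]]
      lastpos <- o_pos[[a2[i]]]
      sigL <- "AG"; sigR <- "GT"
    } else {
      Q <- revcomp(reads[[i]])
      firstpos <- o_pos[[a2[i]]]
      lastpos <- o_pos[[a1[i]]]
      sigL <- "AC"; sigR <- "CT"
    }
    chrom_seq <- genome$sequences[[c1]]
    clen <- nchar(chrom_seq)
    if (!(firstpos > lastpos && lastpos + k <= firstpos)) {
      log[["forward_orientation"]] <- log[["forward_orientation"]] + 1L
      next
    }
    qc <- strsplit(Q, "", fixed = TRUE)[[1L]]
    # donor window: genome starting at the leading anchor
    gw1 <- strsplit(seq_slice(chrom_seq, firstpos,
                              min(firstpos + L, clen)), "",
                    fixed = TRUE)[[1L]]
    mis1 <- c(qc[seq_along(gw1)] != gw1,
              rep(TRUE, L - length(gw1)))
    cum1 <- cumsum(mis1)
    # acceptor window: genome ending at the trailing anchor's end
    acc_lo <- max(lastpos + k - L, 0L)
    gw2 <- strsplit(seq_slice(chrom_seq, acc_lo, lastpos + k), "",
                    fixed = TRUE)[[1L]]
    pad <- L - length(gw2)
    mis2 <- c(rep(TRUE, pad), qc[(pad + 1L):L] != gw2)
    cum2r <- rev(cumsum(rev(mis2)))          # mismatches in Q[j..L]
    cand <- k:(L - k)
    mm_ok <- cum1[cand] + cum2r[cand + 1L] <= mm
    Ss <- lastpos + k - (L - cand)
    Es <- firstpos + cand
    inb <- Ss >= 2L & Es + 2L <= clen
    if (require_splice_signal) {
      sig_ok <- inb &
        substring(chrom_seq, Ss - 1L, Ss) == sigL &
        substring(chrom_seq, Es + 1L, Es + 2L) == sigR
    } else sig_ok <- inb
    valid <- cand[mm_ok & sig_ok]
    if (!length(valid)) {
      log[["no_breakpoint"]] <- log[["no_breakpoint"]] + 1L
      next
    }
    s <- valid[1L]                            # max acceptor-segment length
    log[["called"]] <- log[["called"]] + 1L
    out[[ii]] <- data.frame(read_id = names(reads)[i], chrom = c1,
                            start = lastpos + k - (L - s),
                            end = firstpos + s, strand = s1,
                            read_seq = reads[[i]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(list(empty), out))
  rownames(res) <- NULL
  attr(res, "log") <- log
  res
}

#' Aggregate candidate calls into junctions with per-sample support
#'
#' Calls are grouped by the junction key; support is the number of distinct
#' supporting read sequences per sample (exact duplicates collapse to one).
#' Junctions are kept iff support reaches `min_reads` in at least one sample.
#'
#' @param calls data.frame of [call_backsplice()] rows with an added
#'   `sample` column (or a named list of per-sample call data.frames).
#' @param sample_ids sample universe (columns of the support matrix).
#' @param min_reads detection threshold (default 2 unique reads).
#' @return a [bsj_set()] sorted by (chrom, start, end, strand).
#' @export
aggregate_junctions <- function(calls, sample_ids = NULL, min_reads = 2L) {
  if (is.list(calls) && !is.data.frame(calls)) {
    sample_ids <- sample_ids %||% names(calls)
    calls <- do.call(rbind, lapply(names(calls), function(s) {
      if (!nrow(calls[[s]])) return(NULL)
      cbind(calls[[s]], sample = s, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(calls) || !nrow(calls)) {
    tab <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
    return(bsj_set(tab, matrix(0L, 0L, length(sample_ids),
                               dimnames = list(NULL, sample_ids))))
  }
  sample_ids <- sample_ids %||% sort(unique(calls$sample))
  dt <- data.table::as.data.table(calls)
  dedup <- unique(dt[, c("chrom", "start", "end", "strand", "sample",
                         "read_seq"), with = FALSE])
  sup <- dedup[, list(n = .N), by = c("chrom", "start", "end", "strand",
                                      "sample")]
  keys <- unique(sup[, c("chrom", "start", "end", "strand"), with = FALSE])
  data.table::setorder(keys, chrom, start, end, strand)
  mat <- matrix(0L, nrow(keys), length(sample_ids),
                dimnames = list(NULL, sample_ids))
  kidx <- setNames(seq_len(nrow(keys)), junction_key(keys))
  mat[cbind(kidx[junction_key(sup)], match(sup$sample, sample_ids))] <- sup$n
  keep <- apply(mat, 1L, max) >= min_reads
  bsj_set(as.data.frame(keys)[keep, , drop = FALSE],
          mat[keep, , drop = FALSE], sample_ids)
}

#' One-call junction discovery across samples
#'
#' Builds the anchor index, splits each sample's reads into mapped/unmapped,
#' calls back-splice candidates and aggregates them under the detection rule.
#'
#' @param genome a [genome_bundle()].
#' @param reads_by_sample named list of per-sample read vectors (or FASTQ
#'   paths).
#' @param k anchor length.
#' @param mm mismatch allowance.
#' @param min_reads detection threshold (unique back-spliced reads in at
#'   least one sample).
#' @param require_splice_signal see [call_backsplice()].
#' @return list with `junctions` (a [bsj_set()]), `mapped_totals` (named
#'   integer; SRPBM denominators), and `log` (per-sample drop counters).
#' @export
call_circrnas <- function(genome, reads_by_sample, k = 20L, mm = 0L,
                          min_reads = 2L, require_splice_signal = TRUE) {
  index <- build_anchor_index(genome, k)
  calls <- list()
  mapped <- integer(0)
  logs <- list()
  for (s in names(reads_by_sample)) {
    rd <- reads_by_sample[[s]]
    if (is.character(rd) && length(rd) == 1L && file.exists(rd))
      rd <- read_fastq(rd)
    al <- align_linear(rd, index, genome, mm = mm)
    cc <- call_backsplice(al$unmapped, index, genome, mm = mm,
                          require_splice_signal = require_splice_signal)
    calls[[s]] <- cc
    mapped[[s]] <- al$mapped_count
    logs[[s]] <- attr(cc, "log")
  }
  list(junctions = aggregate_junctions(calls, names(reads_by_sample),
                                       min_reads),
       mapped_totals = mapped, log = logs)
}
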