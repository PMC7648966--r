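# Read-through vs homology-artifact classification of two-gene junctions.
#
# Decision rule: the 50-nt flank on each side of the back-splice junction
# (taken from the spliced circular sequence) is locally aligned against the
# cDNA of both candidate host genes. A flank hitting BOTH genes marks the
# junction as a probable misalignment artifact of a homologous gene pair;
# each flank hitting only its own host marks a true read-through circle.

#' Extract the junction flanks of a circular sequence
#'
#' The acceptor flank is the first `w` nt of the spliced sequence (the
#' sequence downstream of the back-splice junction on the circle); the donor
#' flank is the last `w` nt (ending at the junction). Sequences shorter than
#' `2 * w` are split at the junction.
#'
#' @param spliced_seq circular (spliced) sequence, transcribed strand.
#' @param w flank width in nt (default 50).
#' @return list with `acceptor_flank` and `donor_flank`.
#' @export
extract_flanks <- function(spliced_seq, w = 50L) {
  L <- nchar(spliced_seq)
  if (L == 0L) stopf("empty spliced sequence")
  if (L >= 2L * w) {
    acc <- substr(spliced_seq, 1L, w)
    don <- substr(spliced_seq, L - w + 1L, L)
  } else {
    a <- ceiling(L / 2)
    acc <- substr(spliced_seq, 1L, a)
    don <- substr(spliced_seq, a + 1L, L)
  }
  list(acceptor_flank = acc, donor_flank = don)
}

#' Best local alignment of a query against a subject
#'
#' Smith-Waterman with affine gaps; a gap of length g costs
#' `|gap_open| + g * |gap_extend|`. Both query orientations are tried and
#' the better one reported. A "hit" is declared iff the identity (matches
#' over alignment columns) reaches `min_identity` over an aligned query
#' length of at least `min_length`.
#'
#' @param query,subject DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring (defaults +1/-2/-5/-2).
#' @param min_identity,min_length hit thresholds (defaults 0.8 and 25).
#' @return list with `score`, `identity`, `length` (aligned query bases),
#'   `columns`, `matches`, `orientation` (`"+"`/`"-"`), `hit`.
#' @export
local_align <- function(query, subject, match = 1L, mismatch = -2L,
                        gap_open = -5L, gap_extend = -2L,
                        min_identity = 0.8, min_length = 25L) {
  if (!nchar(query) || !nchar(subject)) stopf("empty sequence")
  run <- function(q) .sw_align(q, subject, match, mismatch,
                               abs(gap_open), abs(gap_extend))
  fwd <- run(query)
  rev <- run(revcomp(query))
  r <- if (rev[["score"]] > fwd[["score"]]) rev else fwd
  ori <- if (rev[["score"]] > fwd[["score"]]) "-" else "+"
  len <- if (r[["score"]] > 0L) r[["q_end"]] - r[["q_start"]] + 1L else 0L
  identity <- if (r[["columns"]] > 0L) r[["matches"]] / r[["columns"]] else 0
  list(score = r[["score"]], identity = identity, length = len,
       columns = r[["columns"]], matches = r[["matches"]], orientation = ori,
       hit = identity >= min_identity && len >= min_length)
}

# does a flank hit any transcript of a gene's cDNA set? returns the best
# alignment, preferring hits, then higher score (order-invariant)
flank_hits_gene <- function(flank, cdnas, ...) {
  als <- lapply(cdnas, function(tx) local_align(flank, tx, ...))
  hits <- vapply(als, `[[`, logical(1), "hit")
  scores <- vapply(als, `[[`, numeric(1), "score")
  pick <- if (any(hits)) which(hits)[which.max(scores[hits])]
          else which.max(scores)
  als[[pick]]
}

#' Classify one two-gene junction as read-through or homology artifact
#'
#' @param flanks result of [extract_flanks()].
#' @param cdna1 character vector of transcript sequences of the upstream
#'   host gene (expected home of the acceptor flank).
#' @param cdna2 transcript sequences of the downstream host gene (expected
#'   home of the donor flank).
#' @param ... thresholds and scoring passed to [local_align()].
#' @return list with `call` (`"true_rt"` or `"homology_artifact"`),
#'   `low_evidence` (a flank missed its own host at the thresholds), and the
#'   four flank-vs-gene alignment summaries.
#' @export
classify_two_gene <- function(flanks, cdna1, cdna2, ...) {
  if (!length(cdna1) || !length(cdna2))
    stopf("missing cDNA for a host gene")
  a1 <- flank_hits_gene(flanks$acceptor_flank, cdna1, ...)
  a2 <- flank_hits_gene(flanks$acceptor_flank, cdna2, ...)
  d1 <- flank_hits_gene(flanks$donor_flank, cdna1, ...)
  d2 <- flank_hits_gene(flanks$donor_flank, cdna2, ...)
  both <- (a1$hit && a2$hit) || (d1$hit && d2$hit)
  call <- if (both) "homology_artifact" else "true_rt"
  low <- !both && (!a1$hit || !d2$hit)
  if (low)
    warnf("low-evidence true_rt call: a flank missed its own host gene")
  list(call = call, low_evidence = low,
       acceptor_vs_g1 = a1, acceptor_vs_g2 = a2,
       donor_vs_g1 = d1, donor_vs_g2 = d2)
}

#' Screen all two-gene records
#'
#' Applies [classify_two_gene()] to every two-gene record, using the
#' concatenated exon sequence of each host gene as its cDNA.
#'
#' @param records annotated records (see [annotate_junctions()]).
#' @param genome a [genome_bundle()].
#' @param w flank width.
#' @param ... thresholds and scoring passed to [local_align()].
#' @return data.frame with one row per two-gene record: junction key
#'   columns, hosts, `call`, `low_evidence`, and per-flank best identities;
#'   attribute `summary` counts calls by class.
#' @export
screen_rt <- function(records, genome, w = 50L, ...) {
  two <- records[records$origin == "two-gene", , drop = FALSE]
  out <- data.frame(name = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), host1 = character(0),
                    host2 = character(0), call = character(0),
                    low_evidence = logical(0),
                    acceptor_id_g1 = numeric(0), acceptor_id_g2 = numeric(0),
                    donor_id_g1 = numeric(0), donor_id_g2 = numeric(0),
                    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(two)), function(i) {
    r <- two[i, ]
    fl <- extract_flanks(r$spliced_seq, w)
    cl <- suppressWarnings(
      classify_two_gene(fl, gene_cdna(genome$genes[[r$host1]],
                                      genome$sequences),
                        gene_cdna(genome$genes[[r$host2]],
                                  genome$sequences), ...))
    data.frame(name = r$name, chrom = r$chrom, start = r$start, end = r$end,
               strand = r$strand, host1 = r$host1, host2 = r$host2,
               call = cl$call, low_evidence = cl$low_evidence,
               acceptor_id_g1 = cl$acceptor_vs_g1$identity,
               acceptor_id_g2 = cl$acceptor_vs_g2$identity,
               donor_id_g1 = cl$donor_vs_g1$identity,
               donor_id_g2 = cl$donor_vs_g2$identity,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(list(out), rows))
  rownames(res) <- NULL
  attr(res, "summary") <- c(true_rt = sum(res$call == "true_rt"),
                            homology_artifact =
                              sum(res$call == "homology_artifact"))
  res
}
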