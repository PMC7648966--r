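# miRNA seed-site counting on circular sequences and ceRNA network export.
#
# Canonical site types against the seed (miRNA nucleotides 2-8; S is the
# reverse complement of the seed on the target):
#   8mer     = S followed by A        (positions 8..2 matched, A opposite 1)
#   7mer-m8  = S                      (positions 8..2)
#   7mer-A1  = S[2..7] followed by A  (positions 7..2, A opposite 1)
#   6mer     = S[2..7]                (positions 7..2)
# Each start position yields at most one site, of its most specific type.
# Sites may wrap past the back-splice junction of the circle.

#' Read a miRNA panel (id, mature sequence)
#'
#' @param path TSV with header columns `mirna_id` and `mature`.
#' @return data.frame with `mirna_id`, `mature` (RNA, uppercase) and `seed`
#'   (nucleotides 2-8).
#' @export
read_mirna_panel <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "mature") %in% names(d)))
    stopf("miRNA panel %s must have columns mirna_id, mature", path)
  d$mature <- dna_to_rna(d$mature)
  if (any(nchar(d$mature) < 8L)) stopf("mature miRNA shorter than 8 nt")
  d$seed <- substr(d$mature, 2L, 8L)
  d
}

#' Circular scan string
#'
#' Appends the first `max_site_len - 1` nt of the sequence (capped at its
#' length) so that sites spanning the back-splice junction are visible to a
#' linear scan; match positions at or beyond the sequence length map back
#' modulo its length.
#'
#' @param spliced_seq circular sequence.
#' @param max_site_len longest site type scanned for (default 8).
#' @return the scan string.
#' @export
circular_scan_sequence <- function(spliced_seq, max_site_len = 8L) {
  if (!nchar(spliced_seq)) stopf("empty sequence")
  paste0(spliced_seq,
         substr(spliced_seq, 1L, min(max_site_len - 1L, nchar(spliced_seq))))
}

#' Canonical seed sites of one miRNA on one circular sequence
#'
#' All (possibly overlapping) occurrences in the circular scan string are
#' reported, each start with its most specific type
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). By default 6mer sites are not counted.
#'
#' @param spliced_seq circular target sequence (DNA or RNA; `T` is read as
#'   `U`).
#' @param mature mature miRNA sequence (RNA, 5'->3'; length >= 8).
#' @param include_6mer also count bare 6mer sites?
#' @return data.frame with `start` (0-based position on the circle, may wrap)
#'   and `type`.
#' @export
seed_sites <- function(spliced_seq, mature, include_6mer = FALSE) {
  pats <- seed_patterns(mature)
  seq_rna <- dna_to_rna(spliced_seq)
  L <- nchar(seq_rna)
  scan <- Biostrings::RNAString(circular_scan_sequence(seq_rna))
  order_types <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
  type_of <- rep(NA_character_, L)
  for (tp in order_types) {   # weakest first; stronger types overwrite
    hits <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::RNAString(pats[[tp]]), scan)) - 1L
    hits <- hits[hits < L]
    type_of[hits + 1L] <- tp
  }
  keep_types <- c("8mer", "7mer-m8", "7mer-A1", if (include_6mer) "6mer")
  keep <- which(type_of %in% keep_types)
  data.frame(start = keep - 1L, type = type_of[keep],
             stringsAsFactors = FALSE)
}

#' Per-(circRNA, miRNA) site count table
#'
#' @param circ_seqs named character vector of circular sequences.
#' @param panel miRNA panel data.frame (`mirna_id`, `mature`).
#' @param include_6mer passed to [seed_sites()].
#' @return data.frame with one row per (circ, miRNA): counts by type and
#'   `n_sites` (total counted sites).
#' @export
sponge_site_table <- function(circ_seqs, panel, include_6mer = FALSE) {
  rows <- list()
  for (ci in names(circ_seqs)) {
    for (mi in seq_len(nrow(panel))) {
      s <- seed_sites(circ_seqs[[ci]], panel$mature[mi], include_6mer)
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = ci, mirna_id = panel$mirna_id[mi],
        n_8mer = sum(s$type == "8mer"),
        n_7mer_m8 = sum(s$type == "7mer-m8"),
        n_7mer_a1 = sum(s$type == "7mer-A1"),
        n_6mer = sum(s$type == "6mer"),
        n_sites = nrow(s), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sponge candidate and top tiers
#'
#' A circRNA is a sponge candidate iff its site count reaches `min_sites`
#' for at least one miRNA, and top-tier iff it reaches `top_sites`.
#'
#' @param site_table output of [sponge_site_table()].
#' @param min_sites candidate threshold (default 5).
#' @param top_sites top-tier threshold (default 10).
#' @return list with `candidates` and `top` (data.frames of qualifying
#'   (circ, miRNA) pairs), `candidate_ids`, `top_ids`, and `matrix` (circ x
#'   miRNA site-count matrix).
#' @export
sponge_candidates <- function(site_table, min_sites = 5L, top_sites = 10L) {
  mat <- matrix(0L, length(unique(site_table$circ_id)),
                length(unique(site_table$mirna_id)),
                dimnames = list(unique(site_table$circ_id),
                                unique(site_table$mirna_id)))
  mat[cbind(site_table$circ_id, site_table$mirna_id)] <- site_table$n_sites
  cand <- site_table[site_table$n_sites >= min_sites, , drop = FALSE]
  top <- site_table[site_table$n_sites >= top_sites, , drop = FALSE]
  list(candidates = cand, top = top,
       candidate_ids = unique(cand$circ_id), top_ids = unique(top$circ_id),
       matrix = mat)
}

#' Build the circRNA-miRNA-mRNA network edge list
#'
#' circRNA-miRNA edges for every candidate pair (weight = site count);
#' miRNA-mRNA edges for every provided target, annotated with the target's
#' differential direction. Targets of miRNAs absent from the panel are
#' skipped with a warning. The summary lists targets that are down-regulated
#' while a candidate circRNA sponging their miRNA is itself down-regulated
#' (reported descriptively).
#'
#' @param candidates `candidates` table from [sponge_candidates()].
#' @param mirna_targets data.frame with `mirna_id`, `gene_id`.
#' @param gene_de optional [de_test()] table for the genes.
#' @param panel miRNA panel (defines the known miRNA universe).
#' @param circ_de optional [de_test()] table for the circRNAs (feature ids
#'   matching `candidates$circ_id`).
#' @return list with `edges` (source, target, interaction, weight,
#'   regulation) and `released_targets` (the descriptive summary).
#' @export
build_network <- function(candidates, mirna_targets, gene_de = NULL,
                          panel = NULL, circ_de = NULL) {
  edges <- data.frame(source = character(0), target = character(0),
                      interaction = character(0), weight = numeric(0),
                      regulation = character(0), stringsAsFactors = FALSE)
  if (nrow(candidates))
    edges <- rbind(edges, data.frame(
      source = candidates$circ_id, target = candidates$mirna_id,
      interaction = "circ-miR", weight = candidates$n_sites,
      regulation = NA_character_, stringsAsFactors = FALSE))
  known <- if (!is.null(panel)) panel$mirna_id else unique(candidates$mirna_id)
  bad <- !mirna_targets$mirna_id %in% known
  if (any(bad)) {
    warnf("%d target edge(s) reference unknown miRNA(s); skipped", sum(bad))
    mirna_targets <- mirna_targets[!bad, , drop = FALSE]
  }
  dir_of <- function(g) {
    if (is.null(gene_de)) return(NA_character_)
    i <- match(g, gene_de$feature_id)
    if (is.na(i)) NA_character_ else gene_de$direction[i]
  }
  if (nrow(mirna_targets))
    edges <- rbind(edges, data.frame(
      source = mirna_targets$mirna_id, target = mirna_targets$gene_id,
      interaction = "miR-mRNA", weight = 1,
      regulation = vapply(mirna_targets$gene_id, dir_of, character(1)),
      stringsAsFactors = FALSE))
  released <- data.frame(circ_id = character(0), mirna_id = character(0),
                         gene_id = character(0), stringsAsFactors = FALSE)
  if (!is.null(circ_de) && !is.null(gene_de) && nrow(candidates)) {
    dn_circ <- circ_de$feature_id[circ_de$direction == "down"]
    for (i in which(candidates$circ_id %in% dn_circ)) {
      tg <- mirna_targets$gene_id[mirna_targets$mirna_id ==
                                    candidates$mirna_id[i]]
      tg <- tg[vapply(tg, dir_of, character(1)) == "down"]
      if (length(tg))
        released <- rbind(released, data.frame(
          circ_id = candidates$circ_id[i],
          mirna_id = candidates$mirna_id[i], gene_id = tg,
          stringsAsFactors = FALSE))
    }
  }
  list(edges = edges, released_targets = released)
}
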