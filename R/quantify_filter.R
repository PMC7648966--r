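# Normalisation (SRPBM for circles, FPKM for genes), the two detection /
# confidence tiers, sample-presence profiles and the circRNA/host-gene
# correlation analysis.

#' Spliced Reads Per Billion Mapped reads
#'
#' `count * 1e9 / total_mapped`.
#'
#' @param count unique back-splice read count(s).
#' @param total_mapped total mapped reads of the sample (> 0).
#' @return numeric SRPBM value(s).
#' @export
srpbm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stopf("total_mapped must be > 0")
  count * 1e9 / total_mapped
}

#' Fragments Per Kilobase of exon per Million fragments mapped
#'
#' `count * 1e9 / (exon_length * total_fragments)`.
#'
#' @param count fragment count(s).
#' @param exon_length length of the gene's exon union in bp (> 0).
#' @param total_fragments total mapped fragments of the sample (> 0).
#' @return numeric FPKM value(s).
#' @export
fpkm <- function(count, exon_length, total_fragments) {
  if (any(exon_length <= 0)) stopf("exon_length must be > 0")
  if (any(total_fragments <= 0)) stopf("total_fragments must be > 0")
  count * 1e9 / (exon_length * total_fragments)
}

#' SRPBM expression table from a count matrix
#'
#' @param cm a [count_matrix()] of back-splice counts with mapped-read
#'   totals.
#' @return numeric matrix of SRPBM values (same dimnames).
#' @export
srpbm_table <- function(cm) {
  sweep(cm$counts, 2L, cm$totals, function(cnt, tot) srpbm(cnt, tot))
}

#' FPKM expression table from a gene count matrix
#'
#' @param cm a [count_matrix()] of gene counts with fragment totals.
#' @param exon_lengths named vector of exon-union lengths (bp) covering the
#'   features of `cm`.
#' @return numeric matrix of FPKM values.
#' @export
fpkm_table <- function(cm, exon_lengths) {
  len <- exon_lengths[rownames(cm$counts)]
  if (anyNA(len)) stopf("missing exon length for some feature")
  t(vapply(seq_len(nrow(cm$counts)), function(i)
    fpkm(cm$counts[i, ], len[i], cm$totals), numeric(ncol(cm$counts)))) |>
    (\(m) { dimnames(m) <- dimnames(cm$counts); m })()
}

#' High-confidence tier filter
#'
#' Keeps a feature iff its count reaches `min_reads` in at least
#' `min_samples` samples of at least one of the two groups.
#'
#' @param cm a [count_matrix()] with exactly two groups, each of at least
#'   `min_samples` samples.
#' @param min_reads per-sample unique-read threshold (default 2).
#' @param min_samples per-group sample threshold (default 4).
#' @return list with `keep` (named logical) and `matrix` (the filtered
#'   [count_matrix()]).
#' @export
tier_filter <- function(cm, min_reads = 2L, min_samples = 4L) {
  grp <- unique(cm$groups)
  if (length(grp) != 2L) stopf("tier_filter requires exactly two groups")
  sizes <- table(cm$groups)
  if (any(sizes < min_samples))
    stopf("group with fewer than min_samples = %d samples", min_samples)
  det <- cm$counts >= min_reads
  keep <- rep(FALSE, nrow(det))
  for (g in grp)
    keep <- keep | rowSums(det[, cm$groups == g, drop = FALSE]) >= min_samples
  names(keep) <- rownames(cm$counts)
  filt <- count_matrix(cm$counts[keep, , drop = FALSE],
                       setNames(cm$totals, colnames(cm$counts)), cm$groups)
  list(keep = keep, matrix = filt)
}

#' Sample-presence profile
#'
#' Counts, per feature, the samples in which it is detected (count >=
#' `min_reads`) and returns the distribution over 0..n_samples.
#'
#' @param cm a [count_matrix()] (groups are not used).
#' @param min_reads detection threshold.
#' @return list with `per_feature` (named integer) and `histogram`
#'   (data.frame over 0..n_samples).
#' @export
presence_profile <- function(cm, min_reads = 2L) {
  n <- ncol(cm$counts)
  per <- rowSums(cm$counts >= min_reads)
  hist <- data.frame(n_samples = 0:n,
                     n_features = vapply(0:n, function(k) sum(per == k),
                                         integer(1)))
  list(per_feature = per, histogram = hist)
}

#' circRNA / host-gene expression correlation
#'
#' Pearson correlation across samples for each (circRNA, host gene) pair and
#' for randomly drawn (circRNA, non-host gene) pairs; the two correlation
#' distributions are compared by a two-sided Wilcoxon rank-sum test.
#' Zero-variance features are excluded and reported.
#'
#' @param circ_expr circRNA expression matrix (e.g. SRPBM), features x
#'   samples.
#' @param gene_expr gene expression matrix (e.g. FPKM), same sample order.
#' @param pairs data.frame with columns `circ` and `host` referencing rows
#'   of the two matrices.
#' @param n_random number of random (circ, non-host gene) pairs.
#' @param seed RNG seed for the random draws (required for reproducibility).
#' @return list with `host` and `random` per-pair tables (`r`, `p`),
#'   `wilcox_p`, and `excluded` (feature ids dropped for zero variance).
#' @export
host_correlation <- function(circ_expr, gene_expr, pairs, n_random = 50L,
                             seed = 1L) {
  if (ncol(circ_expr) < 3L) stopf("need at least 3 samples")
  if (!identical(colnames(circ_expr), colnames(gene_expr)))
    stopf("sample order differs between matrices")
  zv_c <- apply(circ_expr, 1L, function(x) var(x) == 0)
  zv_g <- apply(gene_expr, 1L, function(x) var(x) == 0)
  excluded <- c(rownames(circ_expr)[zv_c], rownames(gene_expr)[zv_g])
  if (all(zv_c) || all(zv_g)) stopf("all features have zero variance")
  ok_pairs <- pairs[pairs$circ %in% rownames(circ_expr)[!zv_c] &
                      pairs$host %in% rownames(gene_expr)[!zv_g], ,
                    drop = FALSE]
  if (!nrow(ok_pairs)) stopf("no usable (circ, host) pair")
  cor_one <- function(circ, gene) {
    ct <- cor.test(circ_expr[circ, ], gene_expr[gene, ], method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  host <- cbind(ok_pairs,
                t(mapply(cor_one, ok_pairs$circ, ok_pairs$host)))
  rnd <- with_seed(seed, {
    genes_ok <- rownames(gene_expr)[!zv_g]
    do.call(rbind, lapply(seq_len(n_random), function(i) {
      circ <- sample(ok_pairs$circ, 1L)
      hostg <- ok_pairs$host[ok_pairs$circ == circ]
      gene <- sample(setdiff(genes_ok, hostg), 1L)
      data.frame(circ = circ, gene = gene, stringsAsFactors = FALSE)
    }))
  })
  random <- cbind(rnd, t(mapply(cor_one, rnd$circ, rnd$gene)))
  wp <- wilcox.test(host$r, random$r, alternative = "two.sided",
                    exact = FALSE)$p.value
  list(host = host, random = random, wilcox_p = wp, excluded = excluded)
}
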