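# Genomic-origin annotation of back-splice junctions.
#
# Origin precedence: two-gene (acceptor in an exon of gene G1, donor in an
# exon of a different same-strand, adjacent gene G2 with G1 transcriptionally
# upstream) > single-gene exonic (CDS / UTR / UTR-CDS by the CDS coverage of
# the junction-bounded exonic nucleotides) > intronic (both ends within one
# gene, either end outside its exons) > intergenic.

# inclusive genomic base of the acceptor / donor end of a junction
acceptor_pos <- function(j) if (j$strand == "+") j$start else j$end - 1L
donor_pos <- function(j) if (j$strand == "+") j$end - 1L else j$start

# exon index (transcription order) containing pos, NA if none
exon_index_at <- function(g, pos) {
  hit <- which(g$exons[, 1L] <= pos & pos < g$exons[, 2L])
  if (length(hit)) hit[1L] else NA_integer_
}

# gene candidates on chrom/strand whose exons contain pos; break ties by an
# exact boundary at the junction edge, then by exonic overlap with the span
host_at <- function(genes, j, pos, want_boundary) {
  cands <- Filter(function(g) g$chrom == j$chrom && g$strand == j$strand &&
                    !is.na(exon_index_at(g, pos)), genes)
  if (!length(cands)) return(NULL)
  if (length(cands) > 1L) {
    exact <- vapply(cands, function(g) {
      i <- exon_index_at(g, pos)
      if (want_boundary == "start") g$exons[i, 1L] == pos
      else g$exons[i, 2L] == pos + 1L
    }, logical(1))
    if (any(exact)) cands <- cands[exact]
  }
  if (length(cands) > 1L) {
    ov <- vapply(cands, function(g)
      sum(pmax(0L, pmin(g$exons[, 2L], j$end) - pmax(g$exons[, 1L],
                                                     j$start))), numeric(1))
    cands <- cands[which.max(ov)]
  }
  cands[[1L]]
}

# no third gene (either strand) between the spans of g1 and g2
genes_adjacent <- function(genes, g1, g2) {
  s1 <- gene_span(g1); s2 <- gene_span(g2)
  lo <- min(s1[2L], s2[2L]); hi <- max(s1[1L], s2[1L])
  if (lo >= hi) return(TRUE)
  for (g in genes) {
    if (g$gene_id %in% c(g1$gene_id, g2$gene_id)) next
    sp <- gene_span(g)
    if (sp[1L] < hi && sp[2L] > lo) return(FALSE)
  }
  TRUE
}

# transcriptionally upstream: g1 before g2 along the shared strand
is_upstream <- function(g1, g2) {
  s1 <- gene_span(g1); s2 <- gene_span(g2)
  if (g1$strand == "+") s1[2L] <= s2[1L] else s1[1L] >= s2[2L]
}

# length of [a,b) covered by the interval union `mat`
covered_length <- function(a, b, mat) {
  if (is.null(mat) || !nrow(mat)) return(0L)
  sum(pmax(0L, pmin(mat[, 2L], b) - pmax(mat[, 1L], a)))
}

#' Assign the genomic origin of one junction
#'
#' @param junction one-row data.frame (or list) with `chrom`, `start`,
#'   `end`, `strand` in the internal 0-based half-open convention.
#' @param genes named list of [gene_model()]s (must cover the junction's
#'   chromosome).
#' @return list with `origin` (one of CDS, UTR-CDS, UTR, intronic,
#'   intergenic, two-gene), `host1`, `host2`, `acceptor_exon`, `donor_exon`
#'   (1-based, transcription order; only when `boundary_exact`) and
#'   `boundary_exact`.
#' @export
assign_origin <- function(junction, genes) {
  j <- as.list(junction)
  if (!j$chrom %in% vapply(genes, `[[`, character(1), "chrom"))
    stopf("chromosome %s absent from the annotation", j$chrom)
  apos <- acceptor_pos(j)
  dpos <- donor_pos(j)
  a_want <- if (j$strand == "+") "start" else "end"
  d_want <- if (j$strand == "+") "end" else "start"
  gA <- host_at(genes, j, apos, a_want)
  gD <- host_at(genes, j, dpos, d_want)

  boundary_exact <- FALSE
  a_idx <- d_idx <- NA_integer_
  res <- function(origin, host1 = NA_character_, host2 = NA_character_)
    list(origin = origin, host1 = host1, host2 = host2,
         acceptor_exon = a_idx, donor_exon = d_idx,
         boundary_exact = boundary_exact)

  exact_at <- function(g, pos, want) {
    i <- exon_index_at(g, pos)
    if (want == "start") g$exons[i, 1L] == pos else g$exons[i, 2L] == pos + 1L
  }

  if (!is.null(gA) && !is.null(gD) && gA$gene_id != gD$gene_id &&
      is_upstream(gA, gD) && genes_adjacent(genes, gA, gD)) {
    boundary_exact <- exact_at(gA, apos, a_want) && exact_at(gD, dpos, d_want)
    a_idx <- exon_index_at(gA, apos)
    d_idx <- exon_index_at(gD, dpos)
    if (!boundary_exact) a_idx <- d_idx <- NA_integer_
    return(res("two-gene", gA$gene_id, gD$gene_id))
  }
  if (!is.null(gA) && !is.null(gD) && gA$gene_id == gD$gene_id) {
    g <- gA
    boundary_exact <- exact_at(g, apos, a_want) && exact_at(g, dpos, d_want)
    if (boundary_exact) {
      a_idx <- exon_index_at(g, apos)
      d_idx <- exon_index_at(g, dpos)
    }
    exonic <- covered_length(j$start, j$end, g$exons)
    in_cds <- covered_length(j$start, j$end, g$cds)
    origin <- if (in_cds == exonic && exonic > 0L && !is.null(g$cds)) "CDS"
              else if (in_cds == 0L) "UTR" else "UTR-CDS"
    return(res(origin, g$gene_id))
  }
  # either end intronic but both within one same-strand gene's span
  within <- Filter(function(g) {
    sp <- gene_span(g)
    g$chrom == j$chrom && g$strand == j$strand &&
      sp[1L] <= j$start && j$end <= sp[2L]
  }, genes)
  if (length(within))
    return(res("intronic", within[[1L]]$gene_id))
  res("intergenic")
}

#' Retrieve the spliced circular sequence of a junction
#'
#' For boundary-exact exonic calls the annotated exon sequences from the
#' acceptor exon through the donor exon are concatenated in transcription
#' order on the transcribed strand (for two-gene circles: upstream-gene exons
#' from the acceptor exon to the gene's last exon, then downstream-gene exons
#' from the first exon to the donor exon). Otherwise the genomic interval
#' `[start, end)` on the transcribed strand is returned.
#'
#' @param junction junction row (`chrom`, `start`, `end`, `strand`).
#' @param origin_call result of [assign_origin()].
#' @param genome a [genome_bundle()].
#' @return list with `seq` (DNA, transcribed strand), `comp_gene`,
#'   `comp_idx` (empty for the genomic fallback).
#' @export
splice_circ_sequence <- function(junction, origin_call, genome) {
  j <- as.list(junction)
  oc <- origin_call
  exonic <- oc$origin %in% c("CDS", "UTR-CDS", "UTR", "two-gene")
  if (exonic && isTRUE(oc$boundary_exact)) {
    if (oc$origin == "two-gene") {
      g1 <- genome$genes[[oc$host1]]
      comp_gene <- c(rep(oc$host1, nrow(g1$exons) - oc$acceptor_exon + 1L),
                     rep(oc$host2, oc$donor_exon))
      comp_idx <- c(oc$acceptor_exon:nrow(g1$exons),
                    seq_len(oc$donor_exon))
    } else {
      comp_gene <- rep(oc$host1, oc$donor_exon - oc$acceptor_exon + 1L)
      comp_idx <- oc$acceptor_exon:oc$donor_exon
    }
    return(list(seq = comp_seq(genome, comp_gene, comp_idx),
                comp_gene = comp_gene, comp_idx = comp_idx))
  }
  s <- seq_slice(genome$sequences[[j$chrom]], j$start, j$end)
  if (j$strand == "-") s <- revcomp(s)
  list(seq = s, comp_gene = character(0), comp_idx = integer(0))
}

#' Annotate a junction set into circRNA records
#'
#' Runs [assign_origin()] and [splice_circ_sequence()] over every junction
#' and assigns names via [name_circrna()].
#'
#' @param junctions a [bsj_set()].
#' @param genome a [genome_bundle()].
#' @return data.frame of circRNA records (one per junction) with origin,
#'   hosts, exon indices, composition, spliced sequence/length, genomic span
#'   and name; row order follows the junction set.
#' @export
annotate_junctions <- function(junctions, genome) {
  tab <- junctions$table
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    j <- tab[i, , drop = FALSE]
    oc <- assign_origin(j, genome$genes)
    sp <- splice_circ_sequence(j, oc, genome)
    data.frame(chrom = j$chrom, start = j$start, end = j$end,
               strand = j$strand, origin = oc$origin, host1 = oc$host1,
               host2 = oc$host2, acceptor_exon = oc$acceptor_exon,
               donor_exon = oc$donor_exon,
               boundary_exact = oc$boundary_exact,
               n_exons = length(sp$comp_idx),
               exon_composition = format_composition(sp$comp_gene,
                                                     sp$comp_idx),
               spliced_seq = sp$seq, spliced_len = nchar(sp$seq),
               genomic_span = j$end - j$start, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$name <- name_circrna(rec)
  rec[, c("name", setdiff(names(rec), "name"))]
}

#' Name circRNA records
#'
#' Single-gene circles are `circ<GENE>_<n>` with `n` the coordinate rank of
#' the junction among that gene's junctions; two-gene circles are
#' `<G1>_e<i>:<G2>_e<j>` with `i` the acceptor exon of the upstream gene and
#' `j` the donor exon of the downstream gene; intergenic circles fall back to
#' `circINTERGENIC_<chrom>_<start>`. Names are made unique.
#'
#' @param records annotated record data.frame (see [annotate_junctions()]).
#' @return character vector of unique names, parallel to `records`.
#' @export
name_circrna <- function(records) {
  n <- nrow(records)
  name <- character(n)
  single <- which(!is.na(records$host1) & records$origin != "two-gene")
  for (g in unique(records$host1[single])) {
    idx <- single[records$host1[single] == g]
    rank <- order(records$start[idx], records$end[idx])
    name[idx[rank]] <- sprintf("circ%s_%d", g, seq_along(idx))
  }
  two <- which(records$origin == "two-gene")
  name[two] <- ifelse(
    is.na(records$acceptor_exon[two]),
    sprintf("%s:%s_%d", records$host1[two], records$host2[two],
            records$start[two]),
    sprintf("%s_e%d:%s_e%d", records$host1[two],
            records$acceptor_exon[two], records$host2[two],
            records$donor_exon[two]))
  inter <- which(is.na(records$host1))
  name[inter] <- sprintf("circINTERGENIC_%s_%d", records$chrom[inter],
                         records$start[inter])
  make.unique(name, sep = "_")
}

#' Feature statistics over annotated records
#'
#' @param records annotated record data.frame.
#' @param genes optional named list of [gene_model()]s (enables the
#'   circRNAs-per-gene-by-exon-count table).
#' @return list of data.frames: `size` (per-record spliced length and
#'   genomic span), `acceptor_exon` (distribution of the most upstream
#'   circularised exon), `per_gene` (circRNAs per host gene and its
#'   distribution), `by_gene_exons` (mean circRNA count per gene, genes
#'   binned by exon count, width 10), `exons_per_circ`.
#' @export
feature_stats <- function(records, genes = NULL) {
  size <- records[, c("name", "spliced_len", "genomic_span")]
  acc <- records$acceptor_exon[!is.na(records$acceptor_exon) &
                                 records$boundary_exact]
  acceptor_exon <- as.data.frame(table(exon = acc), stringsAsFactors = FALSE)
  hosts <- records$host1[!is.na(records$host1)]
  per_gene_counts <- as.data.frame(table(gene_id = hosts),
                                   stringsAsFactors = FALSE)
  per_gene <- as.data.frame(table(n_circ = per_gene_counts$Freq),
                            stringsAsFactors = FALSE)
  exons_per_circ <- as.data.frame(table(
    n_exons = records$n_exons[records$n_exons > 0L]),
    stringsAsFactors = FALSE)
  by_gene_exons <- NULL
  if (!is.null(genes)) {
    ng <- vapply(genes, function(g) nrow(g$exons), integer(1))
    cnt <- setNames(rep(0L, length(genes)), names(genes))
    tabulated <- table(hosts)
    cnt[names(tabulated)] <- as.integer(tabulated)
    bin <- (ng - 1L) %/% 10L
    by_gene_exons <- do.call(rbind, lapply(sort(unique(bin)), function(b)
      data.frame(exon_bin = sprintf("%d-%d", b * 10L + 1L, b * 10L + 10L),
                 n_genes = sum(bin == b),
                 mean_circ = mean(cnt[bin == b]))))
  }
  list(size = size, acceptor_exon = acceptor_exon, per_gene = per_gene,
       per_gene_counts = per_gene_counts, exons_per_circ = exons_per_circ,
       by_gene_exons = by_gene_exons)
}
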