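# Data model and on-disk formats.
#
# Conventions used throughout the package:
#   * all internal coordinates are 0-based half-open [start, end) (BED);
#   * GTF I/O (1-based inclusive) converts at the boundary;
#   * a gene's exons are stored in transcription order, i.e. by descending
#     genomic coordinate for minus-strand genes;
#   * a back-splice junction is keyed by (chrom, start, end, strand) where
#     start/end are the genomic left/right edges of the circularised span.

#' Construct a gene model
#'
#' @param gene_id unique gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix of 0-based half-open exon intervals
#'   in transcription order (descending genomic coordinate on `"-"`).
#' @param cds optional two-column matrix of CDS intervals (subset of the exon
#'   union); `NULL` for non-coding genes.
#' @param biotype `"coding"` or `"noncoding"`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL,
                       biotype = if (is.null(cds)) "noncoding" else "coding") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) stopf("gene %s: empty exon", gene_id)
  g_asc <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(g_asc[-1L, 1L] < g_asc[-nrow(g_asc), 2L]))
    stopf("gene %s: overlapping exons", gene_id)
  expect_order <- if (strand == "+") order(exons[, 1L]) else order(-exons[, 1L])
  if (!identical(expect_order, seq_len(nrow(exons))))
    stopf("gene %s: exons not in transcription order", gene_id)
  if (!is.null(cds) && length(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    ok <- vapply(seq_len(nrow(cds)), function(i) {
      any(g_asc[, 1L] <= cds[i, 1L] & cds[i, 2L] <= g_asc[, 2L])
    }, logical(1))
    if (!all(ok)) stopf("gene %s: CDS outside exons", gene_id)
  } else cds <- NULL
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, biotype = biotype),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s), %s\n", x$gene_id,
              x$chrom, min(x$exons), max(x$exons), x$strand, nrow(x$exons),
              x$biotype))
  invisible(x)
}

gene_span <- function(g) c(min(g$exons[, 1L]), max(g$exons[, 2L]))

# Spliced transcript sequence (exons concatenated in transcription order, on
# the transcribed strand).
gene_cdna <- function(g, sequences) {
  chrom <- sequences[[g$chrom]]
  parts <- vapply(seq_len(nrow(g$exons)), function(i)
    seq_slice(chrom, g$exons[i, 1L], g$exons[i, 2L]), character(1))
  if (g$strand == "-") parts <- revcomp(parts)
  paste(parts, collapse = "")
}

# Length of the exon union (for FPKM).
gene_exon_length <- function(g) sum(g$exons[, 2L] - g$exons[, 1L])

#' Bundle chromosome sequences and gene models
#'
#' Validates that sequences are A/C/G/T/N only and that every gene lies within
#' its chromosome.
#'
#' @param sequences named character vector (or `DNAStringSet`) of chromosome
#'   sequences; uppercased on input.
#' @param genes list of [gene_model()] objects.
#' @return an object of class `genome_bundle` with elements `sequences`
#'   (named uppercase character vector) and `genes` (named list).
#' @export
genome_bundle <- function(sequences, genes = list()) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  sequences <- vapply(sequences, toupper, character(1))
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stopf("chromosome sequences must be named")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stopf("non-ACGTN characters in chromosome(s): %s",
          paste(names(sequences)[bad], collapse = ", "))
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  for (g in genes) {
    if (!g$chrom %in% names(sequences))
      stopf("gene %s on unknown chromosome %s", g$gene_id, g$chrom)
    if (min(g$exons) < 0L || max(g$exons) > nchar(sequences[[g$chrom]]))
      stopf("gene %s outside chromosome %s", g$gene_id, g$chrom)
  }
  structure(list(sequences = sequences, genes = genes),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d chromosome(s), %s bp total, %d gene(s)\n",
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ","),
              length(x$genes)))
  invisible(x)
}

## ---------------------------------------------------------------- FASTA ----

#' Read a FASTA file into a named sequence vector
#'
#' Sequences are uppercased; only A/C/G/T/N are accepted.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  # Biostrings drops invalid letters with only a warning; promote both
  # warnings and errors to a format error so bad records never pass silently
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stopf("malformed FASTA %s: %s", path,
                                            conditionMessage(e)),
                  warning = function(w) stopf("malformed FASTA %s: %s", path,
                                              conditionMessage(w)))
  out <- setNames(toupper(as.character(set)),
                  sub("\\s.*$", "", names(set)))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stopf("FASTA %s: non-ACGTN characters in record(s) %s", path,
          paste(names(out)[bad], collapse = ", "))
  out
}

#' Write named sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    s <- sequences[[nm]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(c(paste0(">", nm),
                 if (nchar(s)) substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

## ------------------------------------------------------------------ GTF ----

#' Read gene models from a GTF file
#'
#' Uses `rtracklayer` for parsing; converts the GTF's 1-based inclusive
#' coordinates to the internal 0-based half-open convention and orders exons
#' in transcription order. Exon/CDS features lacking a `gene_id` are an error.
#'
#' @param path GTF file with gene/transcript/exon/CDS features.
#' @return list of [gene_model()] objects, named by gene id.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  type <- type[keep]
  gid <- as.character(gr$gene_id)
  if (any(is.na(gid) | gid == ""))
    stopf("GTF %s: exon/CDS feature without gene_id", path)
  df <- data.frame(gene_id = gid,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   # GTF 1-based inclusive -> 0-based half-open
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = type, stringsAsFactors = FALSE)
  lapply(split(df, df$gene_id)[unique(df$gene_id)], function(d) {
    strand <- d$strand[1L]
    if (!strand %in% c("+", "-"))
      stopf("gene %s: missing strand in GTF", d$gene_id[1L])
    ex <- unique(d[d$type == "exon", c("start", "end")])
    ex <- ex[order(if (strand == "+") ex$start else -ex$start), , drop = FALSE]
    cds <- d[d$type == "CDS", c("start", "end")]
    cds <- if (nrow(cds)) as.matrix(unique(cds)) else NULL
    gene_model(d$gene_id[1L], d$chrom[1L], strand, as.matrix(ex), cds = cds)
  })
}

#' Write gene models as GTF (one transcript per gene)
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    span <- gene_span(g)
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id,
                      if (is.null(g$cds)) "noncoding" else "protein_coding")
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id,
                      g$gene_id)
    fmt <- function(feat, s, e, attrs)
      sprintf("%s\tcircheart\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, feat, s + 1L, e, g$strand, attrs)
    lines <- c(lines,
               fmt("gene", span[1L], span[2L], attr_g),
               fmt("transcript", span[1L], span[2L], attr_t),
               vapply(seq_len(nrow(g$exons)), function(i)
                 fmt("exon", g$exons[i, 1L], g$exons[i, 2L], attr_t),
                 character(1)),
               if (!is.null(g$cds))
                 vapply(seq_len(nrow(g$cds)), function(i)
                   fmt("CDS", g$cds[i, 1L], g$cds[i, 2L], attr_t),
                   character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

## ------------------------------------------------------------ junctions ----

#' Construct a back-splice junction set
#'
#' A junction set couples a table of unique `(chrom, start, end, strand)`
#' keys with a per-sample matrix of unique supporting-read counts.
#'
#' @param table data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @param support integer matrix, junctions x samples (may have 0 columns).
#' @param sample_ids sample names (column names of `support`).
#' @return an object of class `bsj_set`.
#' @export
bsj_set <- function(table, support = NULL, sample_ids = colnames(support)) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(table)))
  table$start <- as.integer(table$start)
  table$end <- as.integer(table$end)
  if (any(table$start >= table$end)) stopf("junction with start >= end")
  key <- junction_key(table)
  if (anyDuplicated(key)) stopf("duplicate junction keys")
  if (is.null(support))
    support <- matrix(0L, nrow = nrow(table), ncol = 0L)
  support <- as.matrix(support)
  storage.mode(support) <- "integer"
  if (nrow(support) != nrow(table)) stopf("support rows != junctions")
  if (any(support < 0L)) stopf("negative support counts")
  colnames(support) <- sample_ids
  rownames(support) <- key
  rownames(table) <- NULL
  structure(list(table = table, support = support), class = "bsj_set")
}

#' Canonical junction key strings
#'
#' @param table data.frame with `chrom`, `start`, `end` and (if
#'   `strand_aware`) `strand` columns.
#' @param strand_aware include the strand in the key?
#' @return character vector of keys.
#' @export
junction_key <- function(table, strand_aware = TRUE) {
  if (strand_aware)
    paste(table$chrom, table$start, table$end, table$strand, sep = ":")
  else paste(table$chrom, table$start, table$end, sep = ":")
}

#' @export
print.bsj_set <- function(x, ...) {
  cat(sprintf("<bsj_set> %d junction(s), %d sample(s)\n", nrow(x$table),
              ncol(x$support)))
  invisible(x)
}

#' Write junctions as BED6
#'
#' Fields: chrom, start, end, name, score = total unique supporting reads
#' across samples, strand.
#'
#' @param junctions a [bsj_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  tab <- junctions$table
  name <- tab$name %||% sprintf("circ_%d", seq_len(nrow(tab)))
  score <- if (ncol(junctions$support)) rowSums(junctions$support) else 0L
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", tab$chrom, tab$start, tab$end,
                     name, as.integer(score), tab$strand), path)
  invisible(path)
}

#' Read junctions from BED6
#'
#' @param path BED6 file as written by [write_junction_bed()].
#' @return a [bsj_set()] with a single `total` support column holding the BED
#'   score.
#' @export
read_junction_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0L)
    return(bsj_set(data.frame(chrom = character(0), start = integer(0),
                              end = integer(0), strand = character(0))))
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 6L) stopf("BED6 %s: expected 6 columns", path)
  names(d)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(d$end <= d$start)) stopf("BED6 %s: interval with end <= start", path)
  if (!all(d$strand %in% c("+", "-"))) stopf("BED6 %s: bad strand field", path)
  bsj_set(d[, c("chrom", "start", "end", "strand", "name")],
          support = matrix(as.integer(d$score), ncol = 1L,
                           dimnames = list(NULL, "total")))
}

## -------------------------------------------------- counts, samples, fastq ----

#' Construct a count matrix with totals and group labels
#'
#' @param counts integer matrix, features x samples (dimnames required).
#' @param totals per-sample total mapped reads (SRPBM) or fragments (FPKM);
#'   must be positive, named like the columns of `counts`.
#' @param groups named character/factor of group labels per sample.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, totals, groups) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have feature and sample dimnames")
  totals <- totals[colnames(counts)]
  if (anyNA(totals) || any(totals <= 0)) stopf("totals must be > 0 per sample")
  groups <- as.character(groups[colnames(counts)])
  if (anyNA(groups)) stopf("missing group label for some sample")
  structure(list(counts = counts, totals = as.numeric(totals),
                 groups = setNames(groups, colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d feature(s) x %d sample(s); groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s(%d)", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  invisible(x)
}

#' Read a two-column sample sheet (sample_id, group)
#'
#' @param path TSV with header columns `sample_id` and `group`.
#' @return named character vector of group labels.
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d)))
    stopf("sample sheet %s must have columns sample_id, group", path)
  setNames(as.character(d$group), d$sample_id)
}

#' Write a count matrix as TSV (plus totals/groups sidecar)
#'
#' @param cm a [count_matrix()].
#' @param path counts TSV path; a `<path>.samples.tsv` sidecar receives
#'   per-sample totals and groups.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(sample_id = colnames(cm$counts), total = cm$totals,
                     group = unname(cm$groups), stringsAsFactors = FALSE)
  write.table(side, paste0(path, ".samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path counts TSV path (expects the `.samples.tsv` sidecar).
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df[[1L]]
  side <- read.delim(paste0(path, ".samples.tsv"), stringsAsFactors = FALSE)
  count_matrix(counts, setNames(side$total, side$sample_id),
               setNames(side$group, side$sample_id))
}

#' Read single-end FASTQ into a named sequence vector
#'
#' @param path FASTQ file (qualities are ignored).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write single-end FASTQ (constant quality)
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!length(reads)) {
    file.create(path)
    return(invisible(path))
  }
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", names(reads)), unname(reads),
                             "+", qual)), path)
  invisible(path)
}
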