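# Deterministic synthetic fixture: toy genome + annotation, planted circRNAs
# of every genomic-origin class (including read-through circles on an
# independent adjacent gene pair and homology-artifact circles on a mutated
# near-copy pair), per-sample reads, a toy miRNA panel with injected seed
# sites, and truth tables for every stage.
#
# All randomness flows from a single integer seed; sub-stages draw from small
# fixed offsets of it so each stage is individually reproducible.

#' Configuration for the synthetic fixture
#'
#' Defaults emulate the study design the package targets: two groups of five
#' rRNA-depleted single-end libraries, a 95%-identity adjacent homolog pair
#' (the misalignment trap), independent adjacent same-strand pairs as
#' read-through sources, and planted four-fold group differences.
#'
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @param n_samples_per_group samples per group (groups `normal` and `DCM`).
#' @param read_length single-end read length in nt.
#' @param error_rate per-base substitution probability (0 disables errors).
#' @param homolog_identity target sequence identity of the trap pair.
#' @param anchor_margin junction-spanning reads keep at least this many bases
#'   on both sides of the back-splice (matched to the caller's anchor length).
#' @param n_rt_pairs,n_trap_pairs number of read-through / homolog trap gene
#'   pairs (two planted two-gene circles each).
#' @param chrom_length total chromosome length; `NULL` sizes it automatically;
#'   an explicit value smaller than the layout requires is an error at
#'   generation time.
#' @param circ_fc planted circRNA group fold change (DCM over normal).
#' @param gene_fc planted linear-gene group fold change.
#' @param n_mirnas number of toy miRNAs (22-nt) in the panel.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_samples_per_group = 5L, read_length = 100L,
                       error_rate = 0, homolog_identity = 0.95,
                       anchor_margin = 20L, n_rt_pairs = 5L, n_trap_pairs = 5L,
                       chrom_length = NULL, circ_fc = 4, gene_fc = 4,
                       n_mirnas = 8L) {
  stopifnot(homolog_identity >= 0, homolog_identity <= 1, error_rate >= 0,
            error_rate < 1, n_samples_per_group >= 2L, read_length > 2L * anchor_margin)
  panel <- with_seed(seed + 97L, data.frame(
    mirna_id = sprintf("miR-t%d", seq_len(n_mirnas)),
    mature = vapply(seq_len(n_mirnas), function(i)
      dna_to_rna(rand_dna(22L)), character(1)),
    stringsAsFactors = FALSE))
  structure(list(seed = as.integer(seed),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 homolog_identity = homolog_identity,
                 anchor_margin = as.integer(anchor_margin),
                 n_rt_pairs = as.integer(n_rt_pairs),
                 n_trap_pairs = as.integer(n_trap_pairs),
                 chrom_length = chrom_length,
                 circ_fc = circ_fc, gene_fc = gene_fc,
                 mirna_panel = panel),
            class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# iid substitutions at `rate`; a substituted base always differs.
mutate_dna <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    repl <- vapply(ch[hit], function(b) sample(alt[[b]], 1L), character(1))
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

# Map a transcript-side interval [a, b) to genomic offsets within a segment
# of length L on the given strand.
tmap <- function(a, b, L, strand) {
  if (strand == "+") c(a, b) else c(L - b, L - a)
}

# Build one gene as a genomic segment string with exon/intron structure.
# Transcript-side construction guarantees GT..AG introns on the gene strand
# (CT..AC on the genomic plus strand for minus genes).
build_gene_segment <- function(strand, exon_lens, intron_lens) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1L)
  parts <- character(0)
  t_exons <- matrix(0L, nrow = length(exon_lens), ncol = 2L)
  pos <- 0L
  for (i in seq_along(exon_lens)) {
    parts <- c(parts, rand_dna(exon_lens[i]))
    t_exons[i, ] <- c(pos, pos + exon_lens[i])
    pos <- pos + exon_lens[i]
    if (i < length(exon_lens)) {
      parts <- c(parts, paste0("GT", rand_dna(intron_lens[i] - 4L), "AG"))
      pos <- pos + intron_lens[i]
    }
  }
  seg_t <- paste(parts, collapse = "")
  L <- nchar(seg_t)
  g_exons <- t(vapply(seq_len(nrow(t_exons)), function(i)
    tmap(t_exons[i, 1L], t_exons[i, 2L], L, strand), integer(2)))
  list(seg = if (strand == "+") seg_t else revcomp(seg_t),
       exons = g_exons,          # genomic offsets, transcription order
       t_exons = t_exons, length = L)
}

# CDS from the middle of exon c1 to the middle of exon c2 (transcription
# order), expressed as genomic intervals within the segment.
segment_cds <- function(sb, strand, c1, c2) {
  rows <- list()
  for (i in c1:c2) {
    a <- sb$t_exons[i, 1L]
    b <- sb$t_exons[i, 2L]
    mid <- a + (b - a) %/% 2L
    if (i == c1 && i == c2) { a <- mid - 20L; b <- mid + 20L }
    else if (i == c1) a <- mid
    else if (i == c2) b <- mid
    rows[[length(rows) + 1L]] <- tmap(a, b, sb$length, strand)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("start", "end")
  mat
}

# Restore the 2-nt splice signals of a mutated copy (segment coordinates are
# identical to the template's).
restore_splice_signals <- function(seg, template, exons_genomic) {
  g <- exons_genomic[order(exons_genomic[, 1L]), , drop = FALSE]
  for (i in seq_len(nrow(g) - 1L)) {
    is <- g[i, 2L]          # intron start (0-based)
    ie <- g[i + 1L, 1L]     # intron end (exclusive)
    substr(seg, is + 1L, is + 2L) <- substr(template, is + 1L, is + 2L)
    substr(seg, ie - 1L, ie) <- substr(template, ie - 1L, ie)
  }
  seg
}

#' Generate the toy genome and annotation
#'
#' Lays out single genes, read-through source pairs (independent sequences)
#' and homolog trap pairs (downstream gene is a mutated copy of the upstream
#' gene at `homolog_identity`, with splice-site dinucleotides restored) on one
#' chromosome, with intergenic gaps of at least twice the read length, plus a
#' tail region reserved for intergenic circles. Gene roles and layout metadata
#' are attached as the `sim_meta` attribute (consumed by [plant_circrnas()]).
#'
#' @param config a [sim_config()].
#' @return a [genome_bundle()] with attribute `sim_meta`.
#' @export
generate_genome <- function(config) {
  with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  R <- config$read_length
  gap <- function() 2L * R + 20L + sample.int(80L, 1L)

  plan <- list()
  add <- function(gene_id, role, strand, exon_lens, intron_lens, cds_idx,
                  pair_id = NA_character_) {
    plan[[length(plan) + 1L]] <<- list(gene_id = gene_id, role = role,
                                       strand = strand, exon_lens = exon_lens,
                                       intron_lens = intron_lens,
                                       cds_idx = cds_idx, pair_id = pair_id)
  }
  str_of <- function(i) if (i %% 2L == 1L) "+" else "-"

  # dedicated sponge-host genes: one circle each, long exons so that planted
  # miRNA sites fit without overlap
  for (i in 1:3)
    add(sprintf("g%02d", i), "sponge", str_of(i),
        sample(200:240, 9L, replace = TRUE),
        sample(90:150, 8L, replace = TRUE), c(2L, 8L))
  for (i in 4:8)
    add(sprintf("g%02d", i), "ordinary", str_of(i),
        sample(130:240, 9L, replace = TRUE),
        sample(90:150, 8L, replace = TRUE), c(2L, 8L))
  for (i in 9:13)                       # long 5' UTR: exons 2-3 fully UTR
    add(sprintf("g%02d", i), "utr_rich", str_of(i),
        sample(130:240, 7L, replace = TRUE),
        sample(90:150, 6L, replace = TRUE), c(4L, 6L))
  for (i in 14:18) {                    # long intron 3 hosts an intronic circle
    il <- sample(90:150, 5L, replace = TRUE)
    il[3L] <- 600L
    add(sprintf("g%02d", i), "long_intron", str_of(i),
        sample(130:240, 6L, replace = TRUE), il, c(2L, 5L))
  }
  for (i in 19:20)
    add(sprintf("g%02d", i), "noncoding", str_of(i),
        sample(130:240, 5L, replace = TRUE),
        sample(90:150, 4L, replace = TRUE), NULL)
  for (p in seq_len(config$n_rt_pairs)) {
    s <- str_of(p)
    add(sprintf("rt%dA", p), "rt_up", s, sample(150:240, 6L, replace = TRUE),
        sample(90:150, 5L, replace = TRUE), c(2L, 5L), sprintf("rt%d", p))
    add(sprintf("rt%dB", p), "rt_down", s, sample(150:240, 4L, replace = TRUE),
        sample(90:150, 3L, replace = TRUE), c(2L, 3L), sprintf("rt%d", p))
  }
  for (p in seq_len(config$n_trap_pairs)) {
    s <- str_of(p)
    add(sprintf("tp%dA", p), "trap_up", s, sample(150:240, 6L, replace = TRUE),
        sample(90:150, 5L, replace = TRUE), c(2L, 5L), sprintf("tp%d", p))
    # exon/intron structure replaced by a copy of the A gene below
    add(sprintf("tp%dB", p), "trap_down", s, NULL, NULL, c(2L, 5L),
        sprintf("tp%d", p))
  }

  # build segments; trap B genes copy their template with iid substitutions
  segs <- list()
  for (g in plan) {
    if (g$role == "trap_down") {
      tmplt <- segs[[sub("B$", "A", g$gene_id)]]
      sb <- tmplt
      sb$seg <- mutate_dna(tmplt$seg, 1 - config$homolog_identity)
      sb$seg <- restore_splice_signals(sb$seg, tmplt$seg, tmplt$exons)
      segs[[g$gene_id]] <- sb
    } else {
      segs[[g$gene_id]] <- build_gene_segment(g$strand, g$exon_lens,
                                              g$intron_lens)
    }
  }

  # chromosome layout: singles first, then the pairs (members adjacent); for
  # minus-strand pairs the transcriptionally upstream gene is the right one
  offsets <- list()
  lead <- rand_dna(gap())
  chrom_parts <- lead
  pos <- nchar(lead)
  place_gene <- function(gid) {
    offsets[[gid]] <<- pos
    chrom_parts <<- c(chrom_parts, segs[[gid]]$seg)
    pos <<- pos + segs[[gid]]$length
    g <- rand_dna(gap())
    chrom_parts <<- c(chrom_parts, g)
    pos <<- pos + nchar(g)
  }
  singles <- vapply(plan[vapply(plan, function(g) is.na(g$pair_id),
                                logical(1))], `[[`, character(1), "gene_id")
  for (gid in singles) place_gene(gid)
  pair_ids <- unique(stats::na.omit(vapply(plan, function(g)
    g$pair_id %||% NA_character_, character(1))))
  for (pid in pair_ids) {
    members <- plan[vapply(plan, function(g) identical(g$pair_id, pid),
                           logical(1))]
    a <- members[[1L]]$gene_id          # transcriptionally upstream
    b <- members[[2L]]$gene_id
    strand <- members[[1L]]$strand
    lr <- if (strand == "+") c(a, b) else c(b, a)
    offsets[[lr[1L]]] <- pos
    chrom_parts <- c(chrom_parts, segs[[lr[1L]]]$seg)
    pos <- pos + segs[[lr[1L]]]$length
    g <- rand_dna(2L * R + 30L + sample.int(60L, 1L))
    chrom_parts <- c(chrom_parts, g)
    pos <- pos + nchar(g)
    offsets[[lr[2L]]] <- pos
    chrom_parts <- c(chrom_parts, segs[[lr[2L]]]$seg)
    pos <- pos + segs[[lr[2L]]]$length
    g <- rand_dna(gap())
    chrom_parts <- c(chrom_parts, g)
    pos <- pos + nchar(g)
  }
  # tail reserved for intergenic circles: 5 slots of 450 bp
  tail_start <- pos
  tail_seq <- rand_dna(5L * 450L + 200L)
  chrom_parts <- c(chrom_parts, tail_seq)
  pos <- pos + nchar(tail_seq)

  chrom <- paste(chrom_parts, collapse = "")
  if (!is.null(config$chrom_length)) {
    if (config$chrom_length < nchar(chrom))
      stopf("chrom_length %d too small: layout needs %d bp",
            config$chrom_length, nchar(chrom))
    chrom <- paste0(chrom, rand_dna(config$chrom_length - nchar(chrom)))
  }

  genes <- lapply(plan, function(g) {
    sb <- segs[[g$gene_id]]
    off <- offsets[[g$gene_id]]
    exons <- sb$exons + off
    cds <- if (is.null(g$cds_idx)) NULL else segment_cds(sb, g$strand,
                                                         g$cds_idx[1L],
                                                         g$cds_idx[2L]) + off
    gene_model(g$gene_id, "chr1", g$strand, exons, cds = cds,
               biotype = if (is.null(g$cds_idx)) "noncoding" else "coding")
  })

  meta <- list(
    roles = data.frame(
      gene_id = vapply(plan, `[[`, character(1), "gene_id"),
      role = vapply(plan, `[[`, character(1), "role"),
      pair_id = vapply(plan, function(g) g$pair_id %||% NA_character_,
                       character(1)),
      stringsAsFactors = FALSE),
    tail_start = tail_start)
  gb <- genome_bundle(c(chr1 = chrom), genes)
  attr(gb, "sim_meta") <- meta
  gb
}

## ----------------------------------------------------------- truth table ----

# Composition of a circle (vectors of gene ids and 1-based exon indices in
# transcription order) -> junction span, spliced sequence, length.
comp_span <- function(genes, comp_gene, comp_idx) {
  g_first <- genes[[comp_gene[1L]]]
  g_last <- genes[[comp_gene[length(comp_gene)]]]
  acc <- g_first$exons[comp_idx[1L], ]
  don <- g_last$exons[comp_idx[length(comp_idx)], ]
  strand <- g_first$strand
  if (strand == "+") c(start = acc[[1L]], end = don[[2L]])
  else c(start = don[[1L]], end = acc[[2L]])
}

comp_seq <- function(genome, comp_gene, comp_idx) {
  parts <- vapply(seq_along(comp_gene), function(i) {
    g <- genome$genes[[comp_gene[i]]]
    e <- g$exons[comp_idx[i], ]
    s <- seq_slice(genome$sequences[[g$chrom]], e[[1L]], e[[2L]])
    if (g$strand == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

# spliced sequence of one truth row under the current genome state
truth_circ_seq <- function(genome, row) {
  if (row$origin %in% c("intronic", "intergenic")) {
    s <- seq_slice(genome$sequences[[row$chrom]], row$start, row$end)
    if (row$strand == "-") revcomp(s) else s
  } else {
    comp <- parse_composition(row$exon_composition)
    comp_seq(genome, comp$gene, comp$idx)
  }
}

format_composition <- function(gene, idx) paste(paste0(gene, ":", idx),
                                                collapse = ",")

parse_composition <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  list(gene = vapply(parts, `[`, character(1), 1L),
       idx = as.integer(vapply(parts, `[`, character(1), 2L)))
}

#' Plant circRNAs of every origin class and draw per-sample abundances
#'
#' Plants single-gene circles (CDS, UTR-CDS, UTR), intronic and intergenic
#' circles (with canonical splice dinucleotides written into the genome at the
#' planted breakpoints), two true read-through circles on each independent
#' adjacent pair, and two homology-artifact circles on each trap pair.
#' Per-sample back-splice support and per-gene linear counts are drawn here,
#' with planted group fold changes and host-coupled sample factors.
#'
#' @param genome output of [generate_genome()] (with `sim_meta`).
#' @param config the [sim_config()] used to generate the genome.
#' @return list with elements `genome` (possibly edited: planted intronic /
#'   intergenic splice signals), `circ` (truth data.frame incl. per-sample
#'   support columns `support.<sample>`), `gene` (per-gene truth counts) and
#'   `samples` (sample sheet with per-sample depth factors).
#' @export
plant_circrnas <- function(genome, config) {
  with_seed(config$seed + 1L, plant_circrnas_impl(genome, config))
}

plant_circrnas_impl <- function(genome, config) {
  meta <- attr(genome, "sim_meta")
  if (is.null(meta)) stopf("genome lacks sim_meta; use generate_genome()")
  roles <- meta$roles
  chrom <- genome$sequences[["chr1"]]
  n <- config$n_samples_per_group
  samples <- c(sprintf("Nor%d", seq_len(n)), sprintf("DCM%d", seq_len(n)))
  groups <- rep(c("normal", "DCM"), each = n)

  rows <- list()
  add_row <- function(origin, comp_gene, comp_idx, rt_status = "n/a",
                      span = NULL, strand = NULL) {
    if (is.null(span)) {
      span <- comp_span(genome$genes, comp_gene, comp_idx)
      strand <- genome$genes[[comp_gene[1L]]]$strand
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      truth_id = sprintf("t%03d", length(rows) + 1L), chrom = "chr1",
      start = span[[1L]], end = span[[2L]], strand = strand, origin = origin,
      host1 = if (origin == "intergenic") NA_character_ else comp_gene[1L],
      host2 = if (origin == "two-gene") comp_gene[length(comp_gene)]
              else NA_character_,
      acceptor_exon = if (origin %in% c("intronic", "intergenic")) NA_integer_
                      else comp_idx[1L],
      donor_exon = if (origin %in% c("intronic", "intergenic")) NA_integer_
                   else comp_idx[length(comp_idx)],
      exon_composition = if (origin %in% c("intronic", "intergenic")) ""
                         else format_composition(comp_gene, comp_idx),
      rt_status = rt_status, stringsAsFactors = FALSE)
  }
  range_comp <- function(gid, a, d) list(gene = rep(gid, d - a + 1L),
                                         idx = a:d)

  by_role <- function(r) roles$gene_id[roles$role == r]
  for (gid in by_role("sponge")) {             # one fully-CDS circle each
    cc <- range_comp(gid, 3L, 5L)
    add_row("CDS", cc$gene, cc$idx)
  }
  for (gid in by_role("ordinary")) {
    for (ad in list(c(3L, 5L), c(4L, 6L))) {
      cc <- range_comp(gid, ad[1L], ad[2L])
      add_row("CDS", cc$gene, cc$idx)
    }
  }
  for (gid in by_role("ordinary")[1:2]) {      # two extra CDS circles -> 15
    cc <- range_comp(gid, 5L, 7L)
    add_row("CDS", cc$gene, cc$idx)
  }
  for (gid in by_role("ordinary")) {           # exon 2 spans UTR and CDS
    cc <- range_comp(gid, 2L, 4L)
    add_row("UTR-CDS", cc$gene, cc$idx)
  }
  for (gid in by_role("utr_rich")) {
    cc <- range_comp(gid, 3L, 5L)
    add_row("UTR-CDS", cc$gene, cc$idx)
    cc <- range_comp(gid, 2L, 3L)
    add_row("UTR", cc$gene, cc$idx)
  }
  # intronic circles inside the long intron 3 (between exons 3 and 4)
  for (gid in by_role("long_intron")) {
    g <- genome$genes[[gid]]
    iv <- if (g$strand == "+") c(g$exons[3L, 2L], g$exons[4L, 1L])
          else c(g$exons[4L, 2L], g$exons[3L, 1L])
    S <- iv[1L] + 60L
    E <- S + 280L
    sig <- if (g$strand == "+") c("AG", "GT") else c("AC", "CT")
    substr(chrom, S - 1L, S) <- sig[1L]
    substr(chrom, E + 1L, E + 2L) <- sig[2L]
    add_row("intronic", gid, NA_integer_, span = c(S, E), strand = g$strand)
  }
  # intergenic circles in the reserved tail
  for (j in 1:5) {
    S <- meta$tail_start + (j - 1L) * 450L + 80L
    E <- S + 260L
    substr(chrom, S - 1L, S) <- "AG"
    substr(chrom, E + 1L, E + 2L) <- "GT"
    add_row("intergenic", NA_character_, NA_integer_, span = c(S, E),
            strand = "+")
  }
  # two-gene circles: acceptor exon 4 of the upstream gene, donor exon 1 or 2
  # of the downstream gene (the read-through topology)
  two_gene <- function(a_gid, b_gid, donor_idx, rt_status) {
    gA <- genome$genes[[a_gid]]
    comp_gene <- c(rep(a_gid, nrow(gA$exons) - 3L), rep(b_gid, donor_idx))
    comp_idx <- c(4:nrow(gA$exons), seq_len(donor_idx))
    add_row("two-gene", comp_gene, comp_idx, rt_status = rt_status)
  }
  for (p in seq_len(config$n_rt_pairs)) {
    two_gene(sprintf("rt%dA", p), sprintf("rt%dB", p), 1L, "true_rt")
    two_gene(sprintf("rt%dA", p), sprintf("rt%dB", p), 2L, "true_rt")
  }
  for (p in seq_len(config$n_trap_pairs)) {
    two_gene(sprintf("tp%dA", p), sprintf("tp%dB", p), 1L, "homology_artifact")
    two_gene(sprintf("tp%dA", p), sprintf("tp%dB", p), 2L, "homology_artifact")
  }

  circ <- do.call(rbind, rows)
  genome$sequences[["chr1"]] <- chrom

  # planted abundances -------------------------------------------------------
  # shared per-sample depth factor and per-(gene, sample) biological factor;
  # host circles inherit their host gene's biological factor so that the
  # circRNA/host-gene correlation is real
  depth <- exp(rnorm(length(samples), 0, 0.25))
  names(depth) <- samples
  gene_ids <- names(genome$genes)
  bio <- matrix(exp(rnorm(length(gene_ids) * length(samples), 0, 0.4)),
                nrow = length(gene_ids),
                dimnames = list(gene_ids, samples))

  # planted circRNA fold changes: 5 up / 5 down single-gene circles plus both
  # circles of the first rt pair down (the paper-style rt dysregulation)
  single_idx <- which(circ$origin %in% c("CDS", "UTR-CDS", "UTR"))
  de_up <- single_idx[1:5]
  de_dn <- single_idx[6:10]
  rt1 <- which(circ$host1 == "rt1A" & circ$origin == "two-gene")
  circ$base <- sample(3:8, nrow(circ), replace = TRUE)
  circ$fc <- 1
  circ$base[de_up] <- 5L;  circ$fc[de_up] <- config$circ_fc
  circ$base[de_dn] <- 20L; circ$fc[de_dn] <- 1 / config$circ_fc
  circ$base[rt1] <- 20L;   circ$fc[rt1] <- 1 / config$circ_fc

  # support is bounded above by the number of distinct callable breakpoint
  # offsets a junction read can take (read_length - 2 * anchor_margin + 1)
  sup_cap <- config$read_length - 2L * config$anchor_margin + 1L
  support <- matrix(0L, nrow(circ), length(samples),
                    dimnames = list(circ$truth_id, samples))
  for (i in seq_len(nrow(circ))) {
    hostf <- if (!is.na(circ$host1[i])) bio[circ$host1[i], ] else rep(1, length(samples))
    mu <- circ$base[i] * ifelse(groups == "DCM", circ$fc[i], 1) *
      depth * hostf
    support[i, ] <- pmin(sup_cap, pmax(3L, rpois(length(samples), mu)))
  }
  circ <- cbind(circ, setNames(as.data.frame(support),
                               paste0("support.", samples)))

  # linear gene counts (gene-level counting itself is an input to the
  # pipeline, not something the toy aligner recomputes)
  gene_base <- round(runif(length(gene_ids), 20, 60))
  gene_fc <- rep(1, length(gene_ids))
  coding <- which(vapply(genome$genes, function(g) g$biotype == "coding",
                         logical(1)))
  gene_fc[coding[1:4]] <- config$gene_fc
  gene_fc[coding[5:8]] <- 1 / config$gene_fc
  gcounts <- matrix(0L, length(gene_ids), length(samples),
                    dimnames = list(gene_ids, samples))
  for (i in seq_along(gene_ids)) {
    mu <- gene_base[i] * ifelse(groups == "DCM", gene_fc[i], 1) * depth *
      bio[i, ]
    gcounts[i, ] <- rpois(length(samples), mu)
  }
  gene <- data.frame(gene_id = gene_ids,
                     biotype = vapply(genome$genes, `[[`, character(1),
                                      "biotype"),
                     exon_length = vapply(genome$genes, gene_exon_length,
                                          numeric(1)),
                     base = gene_base, fc = gene_fc,
                     stringsAsFactors = FALSE)
  gene <- cbind(gene, setNames(as.data.frame(gcounts),
                               paste0("count.", samples)))
  rownames(gene) <- NULL

  # spliced sequences under the current genome (refreshed again after miRNA
  # site planting)
  circ$spliced_seq <- vapply(seq_len(nrow(circ)), function(i)
    truth_circ_seq(genome, circ[i, ]), character(1))
  circ$spliced_len <- nchar(circ$spliced_seq)
  if (any(circ$spliced_len < config$read_length))
    stopf("planted circle shorter than the read length")

  list(genome = genome, circ = circ, gene = gene,
       samples = data.frame(sample_id = samples, group = groups,
                            depth_factor = unname(depth),
                            stringsAsFactors = FALSE))
}

## ------------------------------------------------------------ miRNA sites ----

# seed (nt 2-8) match patterns on the target, most specific first
seed_patterns <- function(mature) {
  seed <- substr(toupper(mature), 2L, 8L)
  if (grepl("[^ACGU]", seed)) stopf("seed contains non-ACGU characters")
  S <- dna_to_rna(revcomp(rna_to_dna(seed)))
  c(`8mer` = paste0(S, "A"), `7mer-m8` = S,
    `7mer-A1` = paste0(substr(S, 2L, 7L), "A"), `6mer` = substr(S, 2L, 7L))
}

# generator-internal site scan (kept separate from the sponge module's
# scanner): per-start substring comparison on the circular scan string, with
# the most specific type winning at each start
gen_scan_sites <- function(seq_rna, mature, types = c("8mer", "7mer-m8",
                                                      "7mer-A1")) {
  pats <- seed_patterns(mature)
  L <- nchar(seq_rna)
  scan <- paste0(seq_rna, substr(seq_rna, 1L, min(7L, L)))
  p1 <- seq_len(L)                       # 1-based starts
  type <- rep(NA_character_, L)
  type[substring(scan, p1, p1 + 5L) == pats[["6mer"]]] <- "6mer"
  type[substring(scan, p1, p1 + 6L) == pats[["7mer-A1"]]] <- "7mer-A1"
  type[substring(scan, p1, p1 + 6L) == pats[["7mer-m8"]]] <- "7mer-m8"
  type[substring(scan, p1, p1 + 7L) == pats[["8mer"]]] <- "8mer"
  keep <- !is.na(type) & type %in% types
  data.frame(start = p1[keep] - 1L, type = type[keep],
             stringsAsFactors = FALSE)
}

# map a circle position of a truth row to (genomic position, strand)
circpos_to_genome <- function(genome, row, q) {
  if (row$origin %in% c("intronic", "intergenic")) {
    if (row$strand == "+") c(pos = row$start + q, minus = 0L)
    else c(pos = row$end - 1L - q, minus = 1L)
  } else {
    comp <- parse_composition(row$exon_composition)
    for (i in seq_along(comp$gene)) {
      g <- genome$genes[[comp$gene[i]]]
      e <- g$exons[comp$idx[i], ]
      w <- e[[2L]] - e[[1L]]
      if (q < w) {
        if (g$strand == "+") return(c(pos = e[[1L]] + q, minus = 0L))
        return(c(pos = e[[2L]] - 1L - q, minus = 1L))
      }
      q <- q - w
    }
    stopf("circle position beyond spliced length")
  }
}

genome_edit_circpos <- function(genome, row, q, base_rna) {
  m <- circpos_to_genome(genome, row, q)
  b <- rna_to_dna(base_rna)
  if (m[["minus"]] == 1L) b <- revcomp(b)
  s <- genome$sequences[[row$chrom]]
  substr(s, m[["pos"]] + 1L, m[["pos"]] + 1L) <- b
  genome$sequences[[row$chrom]] <- s
  genome
}

default_site_plan <- function() list(
  list(slot = 1L, mirna = "miR-t1",
       sites = c(`8mer` = 4L, `7mer-m8` = 5L, `7mer-A1` = 3L),
       junction_spanning = TRUE),
  list(slot = 1L, mirna = "miR-t2", sites = c(`8mer` = 2L, `7mer-m8` = 4L)),
  list(slot = 2L, mirna = "miR-t2", sites = c(`7mer-m8` = 3L, `7mer-A1` = 2L)),
  list(slot = 3L, mirna = "miR-t3", sites = c(`7mer-m8` = 2L, `7mer-A1` = 2L)))

#' Inject miRNA seed-match sites into planted circle sequences
#'
#' Selected circles (the dedicated single-circle sponge hosts) receive an
#' exact number of non-overlapping canonical sites per miRNA, including one
#' site spanning the back-splice junction. Before injection, accidental
#' occurrences of any counted site type (8mer, 7mer-m8, 7mer-A1) for any
#' panel miRNA are scrubbed from every planted circle by single-base genome
#' edits, so the truth counts are exact. The genome is edited in place;
#' spliced sequences in the truth table are recomputed.
#'
#' @param genome genome bundle (as returned inside [plant_circrnas()]).
#' @param truth the list returned by [plant_circrnas()].
#' @param config the [sim_config()].
#' @return list(genome, truth, sites) where `sites` is the per
#'   (circRNA, miRNA) truth table of planted counts by type.
#' @export
plant_mirna_sites <- function(genome, truth, config) {
  with_seed(config$seed + 2L, plant_mirna_sites_impl(genome, truth, config))
}

plant_mirna_sites_impl <- function(genome, truth, config) {
  circ <- truth$circ
  panel <- config$mirna_panel
  plan <- default_site_plan()
  sponge_rows <- which(circ$origin == "CDS" &
                         circ$host1 %in% sprintf("g%02d", 1:3))
  stopifnot(length(sponge_rows) >= 3L)

  planted <- list()   # per circ row index: circle positions of planted sites
  reserve <- function(ri, p, w, L) {
    key <- as.character(ri)
    planted[[key]] <<- union(planted[[key]] %||% integer(0),
                             (p + seq_len(w) - 1L) %% L)
  }
  # first position of the accidental site [p, p+w) that is free of planted
  # bases (NA if the site is fully nested in planted sites)
  free_scrub_pos <- function(ri, p, w, L) {
    pos <- (p + seq_len(w) - 1L) %% L
    taken <- planted[[as.character(ri)]] %||% integer(0)
    free <- pos[!pos %in% taken]
    # prefer the core of the heptamer when it is free
    core <- (p + 3L) %% L
    if (core %in% free) core else if (length(free)) free[1L] else NA_integer_
  }

  refresh <- function() {
    circ$spliced_seq <<- vapply(seq_len(nrow(circ)), function(i)
      truth_circ_seq(genome, circ[i, ]), character(1))
  }

  # one scrub pass: break every accidental counted-type occurrence (outside
  # planted intervals) with a single substitution in its core; returns the
  # number of edits applied
  scrub_pass <- function() {
    refresh()
    edits <- 0L
    for (ri in seq_len(nrow(circ))) {
      seq_rna <- dna_to_rna(circ$spliced_seq[ri])
      L <- nchar(seq_rna)
      for (mi in seq_len(nrow(panel))) {
        hits <- gen_scan_sites(seq_rna, panel$mature[mi])
        if (!nrow(hits)) next
        pats <- seed_patterns(panel$mature[mi])
        for (hi in seq_len(nrow(hits))) {
          w <- nchar(pats[[hits$type[hi]]])
          q <- free_scrub_pos(ri, hits$start[hi], w, L)
          if (is.na(q)) next     # fully nested in planted sites: accounted
          cur <- substr(seq_rna, q + 1L, q + 1L)
          repl <- setdiff(c("A", "C", "G", "U"), cur)[1L]
          genome <<- genome_edit_circpos(genome, circ[ri, ], q, repl)
          edits <- edits + 1L
        }
      }
    }
    edits
  }
  scrub_until_clean <- function(stage) {
    for (iter in 1:12) {
      if (scrub_pass() == 0L) return(invisible())
    }
    stopf("site scrubbing did not converge (%s)", stage)
  }

  # 1) scrub accidental counted-type occurrences everywhere
  scrub_until_clean("pre-injection")

  # 2) inject planned sites at fixed, non-overlapping circle positions
  site_rows <- list()
  for (pl in plan) {
    ri <- sponge_rows[pl$slot]
    row <- circ[ri, ]
    L <- row$spliced_len
    pats <- seed_patterns(panel$mature[panel$mirna_id == pl$mirna])
    # disjoint position bands when two miRNAs target the same circle
    cursor <- 12L + 330L * ((match(pl$mirna, panel$mirna_id) - 1L) %% 2L)
    # separate miRNAs on the same circle into disjoint position bands
    n_linear <- sum(pl$sites) - as.integer(isTRUE(pl$junction_spanning))
    types <- rep(names(pl$sites), pl$sites)
    if (isTRUE(pl$junction_spanning)) {
      jtype <- if (any(types == "7mer-m8")) "7mer-m8" else types[1L]
      types <- types[-match(jtype, types)]
    }
    poss <- cursor + 28L * (seq_along(types) - 1L)
    if (length(poss) && max(poss) + 9L > L)
      stopf("planted sites exceed circle capacity")
    write_site <- function(p, tp) {
      # guard base C after the site so the background cannot extend it into
      # an unplanned longer type (e.g. an A after a 7mer-m8 makes a 7mer-A1)
      pat <- c(strsplit(pats[[tp]], "")[[1L]], "C")
      for (o in seq_along(pat))
        genome <<- genome_edit_circpos(genome, row, (p + o - 1L) %% L,
                                       pat[o])
      reserve(ri, p, length(pat), L)
    }
    for (i in seq_along(types)) write_site(poss[i], types[i])
    jspan <- 0L
    if (isTRUE(pl$junction_spanning)) {
      write_site(L - 3L, "7mer-m8")    # wraps 4 nt past the junction
      jspan <- 1L
    }
    cnt <- c(`8mer` = 0L, `7mer-m8` = 0L, `7mer-A1` = 0L)
    full_types <- rep(names(pl$sites), pl$sites)
    for (tp in names(cnt)) cnt[tp] <- sum(full_types == tp)
    # under per-start most-specific typing every 8mer (S+A) carries a nested
    # 7mer-A1 (S[2..7]+A) at the next start; the truth counts include it
    cnt[["7mer-A1"]] <- cnt[["7mer-A1"]] + cnt[["8mer"]]
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      truth_id = row$truth_id, mirna_id = pl$mirna,
      n_8mer = cnt[["8mer"]], n_7mer_m8 = cnt[["7mer-m8"]],
      n_7mer_a1 = cnt[["7mer-A1"]], n_junction_spanning = jspan,
      stringsAsFactors = FALSE)
  }

  # 3) re-scrub accidental occurrences created by injection (never touching
  # planted intervals), then verify truth counts exactly
  scrub_until_clean("post-injection")

  # complete the (circ x miRNA) truth grid with zeros and verify
  sites <- expand.grid(truth_id = circ$truth_id, mirna_id = panel$mirna_id,
                       stringsAsFactors = FALSE)
  sites$n_8mer <- 0L
  sites$n_7mer_m8 <- 0L
  sites$n_7mer_a1 <- 0L
  sites$n_junction_spanning <- 0L
  for (sr in site_rows) {
    k <- sites$truth_id == sr$truth_id & sites$mirna_id == sr$mirna_id
    sites[k, c("n_8mer", "n_7mer_m8", "n_7mer_a1", "n_junction_spanning")] <-
      sr[, c("n_8mer", "n_7mer_m8", "n_7mer_a1", "n_junction_spanning")]
  }
  refresh()
  circ$spliced_len <- nchar(circ$spliced_seq)
  for (k in seq_len(nrow(sites))) {
    row <- circ[circ$truth_id == sites$truth_id[k], ]
    hits <- gen_scan_sites(dna_to_rna(row$spliced_seq),
                           panel$mature[panel$mirna_id == sites$mirna_id[k]])
    got <- c(sum(hits$type == "8mer"), sum(hits$type == "7mer-m8"),
             sum(hits$type == "7mer-A1"))
    want <- as.integer(sites[k, c("n_8mer", "n_7mer_m8", "n_7mer_a1")])
    if (!identical(got, want))
      stopf("site planting verification failed for %s x %s",
            sites$truth_id[k], sites$mirna_id[k])
  }

  truth$circ <- circ
  list(genome = genome, truth = truth, sites = sites)
}

## ---------------------------------------------------------------- reads ----

#' Simulate per-sample single-end reads
#'
#' Linear reads are drawn from spliced transcript sequences in proportion to
#' the planted gene counts. Each planted circle receives exactly its planted
#' number of distinct junction-spanning reads per sample (breakpoint kept at
#' least `anchor_margin` nt from both read ends) plus an equal number of
#' non-junction circular reads. Substitution errors are applied at
#' `error_rate`.
#'
#' @param genome genome bundle (after site planting).
#' @param truth truth list (after site planting).
#' @param config the [sim_config()].
#' @return list with `reads` (named character vector per sample; names encode
#'   provenance) and `samples` (sample table with read and expected-mapped
#'   totals).
#' @export
simulate_reads <- function(genome, truth, config) {
  with_seed(config$seed + 3L, simulate_reads_impl(genome, truth, config))
}

simulate_reads_impl <- function(genome, truth, config) {
  R <- config$read_length
  k <- config$anchor_margin
  circ <- truth$circ
  gene <- truth$gene
  samples <- truth$samples$sample_id
  if (any(circ$spliced_len < R))
    stopf("read length %d exceeds a planted circle length", R)

  cdna <- vapply(genome$genes, gene_cdna, character(1),
                 sequences = genome$sequences)
  # forward-splice boundary inside two-gene circles that no annotated
  # transcript contains (reads crossing it cannot be linearly mapped)
  rt_boundary <- rep(NA_integer_, nrow(circ))
  for (i in which(circ$origin == "two-gene")) {
    comp <- parse_composition(circ$exon_composition[i])
    gA <- comp$gene[1L]
    lenA <- sum(vapply(which(comp$gene == gA), function(j) {
      e <- genome$genes[[gA]]$exons[comp$idx[j], ]
      e[[2L]] - e[[1L]]
    }, numeric(1)))
    rt_boundary[i] <- lenA
  }

  out <- list()
  sample_stats <- truth$samples
  sample_stats$n_reads <- 0L
  sample_stats$n_mapped_expected <- 0L

  for (si in seq_along(samples)) {
    s <- samples[si]
    reads <- character(0)
    ids <- character(0)
    n_mapped <- 0L

    # linear transcript reads
    for (gi in seq_len(nrow(gene))) {
      cnt <- gene[[paste0("count.", s)]][gi]
      if (cnt == 0L) next
      tx <- cdna[[gene$gene_id[gi]]]
      starts <- sample.int(nchar(tx) - R + 1L, cnt, replace = TRUE) - 1L
      reads <- c(reads, substring(tx, starts + 1L, starts + R))
      ids <- c(ids, sprintf("%s:lin:%s:%d", s, gene$gene_id[gi],
                            seq_len(cnt)))
      n_mapped <- n_mapped + cnt
    }

    # circular reads
    for (ci in seq_len(nrow(circ))) {
      L <- circ$spliced_len[ci]
      dbl <- paste0(circ$spliced_seq[ci], circ$spliced_seq[ci])
      sup <- circ[[paste0("support.", s)]][ci]
      if (sup > R - 2L * k + 1L)
        stopf("planted support %d exceeds the %d distinct breakpoint offsets",
              sup, R - 2L * k + 1L)
      # junction-spanning: breakpoint offset j0 in [k, R-k]
      repeat {
        j0 <- sample(seq.int(k, R - k), sup, replace = FALSE)
        p <- L - j0
        jr <- substring(dbl, p + 1L, p + R)
        if (!anyDuplicated(jr)) break
      }
      reads <- c(reads, jr)
      ids <- c(ids, sprintf("%s:bsj:%s:%d", s, circ$truth_id[ci],
                            seq_len(sup)))
      # background circular reads: crossing neither the back-splice nor (for
      # two-gene circles) the unannotated read-through boundary, so every
      # background read is linearly mappable by construction
      allowed <- 0:(L - R)
      b <- rt_boundary[ci]
      if (!is.na(b))
        allowed <- allowed[!(allowed < b & allowed + R > b)]
      p2 <- sample(allowed, sup, replace = TRUE)
      br <- substring(dbl, p2 + 1L, p2 + R)
      reads <- c(reads, br)
      ids <- c(ids, sprintf("%s:cbg:%s:%d", s, circ$truth_id[ci],
                            seq_len(sup)))
      n_mapped <- n_mapped + length(br)
    }

    # one exact duplicate junction read in the first sample exercises the
    # unique-read collapse rule without changing the truth support
    if (si == 1L) {
      first_j <- which(startsWith(ids, sprintf("%s:bsj:%s:", s,
                                               circ$truth_id[1L])))[1L]
      reads <- c(reads, reads[first_j])
      ids <- c(ids, paste0(ids[first_j], ":dup"))
    }

    if (config$error_rate > 0)
      reads <- vapply(reads, mutate_dna, character(1),
                      rate = config$error_rate, USE.NAMES = FALSE)
    names(reads) <- ids
    out[[s]] <- reads
    sample_stats$n_reads[si] <- length(reads)
    sample_stats$n_mapped_expected[si] <- n_mapped
  }
  list(reads = out, samples = sample_stats)
}

## -------------------------------------------------------------- fixture ----

#' Generate the complete synthetic fixture on disk
#'
#' Runs [generate_genome()], [plant_circrnas()], [plant_mirna_sites()] and
#' [simulate_reads()] in order and writes genome FASTA, annotation GTF,
#' per-sample FASTQ, sample sheet, miRNA panel, miRNA target lists, and truth
#' TSVs under one output directory.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory objects (`genome`, `truth`,
#'   `sites`, `reads`, `paths`).
#' @export
simulate_fixture <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  pt <- plant_circrnas(genome, config)
  genome <- pt$genome
  ps <- plant_mirna_sites(genome, pt, config)
  genome <- ps$genome
  truth <- ps$truth
  truth$gene <- pt$gene
  rd <- simulate_reads(genome, truth, config)
  truth$samples <- rd$samples

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    samples = file.path(out_dir, "samples.tsv"),
    mirna = file.path(out_dir, "mirna_panel.tsv"),
    targets = file.path(out_dir, "mirna_targets.tsv"),
    gene_counts = file.path(out_dir, "gene_counts.tsv"),
    truth_circ = file.path(out_dir, "truth_circ.tsv"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    truth_samples = file.path(out_dir, "truth_samples.tsv"),
    reads = setNames(file.path(out_dir,
                               paste0(truth$samples$sample_id, ".fastq")),
                     truth$samples$sample_id))
  write_fasta(genome$sequences, paths$genome)
  write_gtf(genome$genes, paths$gtf)
  write.table(truth$samples[, c("sample_id", "group")], paths$samples,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(config$mirna_panel, paths$mirna, sep = "\t", quote = FALSE,
              row.names = FALSE)
  # toy miRNA target lists: miR-t1 targets the planted down-regulated coding
  # genes (the release-of-repression pattern), miR-t2/t3 targets are neutral
  coding <- truth$gene$gene_id[truth$gene$biotype == "coding"]
  dn <- truth$gene$gene_id[truth$gene$fc < 1][1:2]
  targets <- data.frame(
    mirna_id = c("miR-t1", "miR-t1", "miR-t1", "miR-t2", "miR-t2", "miR-t3"),
    gene_id = c(dn, coding[9L], coding[10L], coding[11L], coding[12L]),
    stringsAsFactors = FALSE)
  write.table(targets, paths$targets, sep = "\t", quote = FALSE,
              row.names = FALSE)
  gc_mat <- as.matrix(truth$gene[, paste0("count.",
                                          truth$samples$sample_id)])
  dimnames(gc_mat) <- list(truth$gene$gene_id, truth$samples$sample_id)
  write_count_matrix(count_matrix(gc_mat,
                                  setNames(truth$samples$n_mapped_expected,
                                           truth$samples$sample_id),
                                  setNames(truth$samples$group,
                                           truth$samples$sample_id)),
                     paths$gene_counts)
  write.table(truth$circ, paths$truth_circ, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ps$sites, paths$truth_sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$samples, paths$truth_samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (s in names(rd$reads)) write_fastq(rd$reads[[s]], paths$reads[[s]])

  invisible(list(genome = genome, truth = truth, sites = ps$sites,
                 reads = rd$reads, targets = targets, config = config,
                 paths = paths))
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Two groups with equal library sizes; feature-wise means `mu`, common
#' dispersion `phi`, and an optional subset of features with a planted log2
#' fold change.
#'
#' @param n_features number of features.
#' @param n_per_group samples per group.
#' @param mu baseline mean count.
#' @param phi NB dispersion (0 gives Poisson counts).
#' @param n_de number of planted differential features (prefix of the rows).
#' @param lfc log2 fold change applied to group B of the planted features.
#' @param seed RNG seed.
#' @return a [count_matrix()] with groups `A`/`B` and equal totals; planted
#'   rows are named `de_*`, nulls `null_*`.
#' @export
simulate_nb_counts <- function(n_features, n_per_group = 5L, mu = 20,
                               phi = 0.1, n_de = 0L, lfc = 2, seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_group
    mu_mat <- matrix(mu, n_features, n)
    if (n_de > 0L)
      mu_mat[seq_len(n_de), (n_per_group + 1L):n] <- mu * 2^lfc
    counts <- matrix(0L, n_features, n)
    for (j in seq_len(n)) {
      counts[, j] <- if (phi > 0)
        rnbinom(n_features, size = 1 / phi, mu = mu_mat[, j])
      else rpois(n_features, mu_mat[, j])
    }
    dimnames(counts) <- list(
      c(if (n_de > 0L) sprintf("de_%d", seq_len(n_de)),
        sprintf("null_%d", seq_len(n_features - n_de))),
      sprintf("S%02d", seq_len(n)))
    grp <- setNames(rep(c("A", "B"), each = n_per_group), colnames(counts))
    count_matrix(counts, setNames(rep(1e6, n), colnames(counts)), grp)
  })
}
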