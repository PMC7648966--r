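# Shared fixture and pipeline run, generated once per test session.

.fx_cache <- new.env(parent = emptyenv())

demo_fixture <- function() {
  if (is.null(.fx_cache$fx)) {
    dir <- tempfile("circheart_fx_")
    .fx_cache$fx <- simulate_fixture(sim_config(seed = 1), dir)
  }
  .fx_cache$fx
}

demo_pipeline <- function() {
  if (is.null(.fx_cache$run)) {
    fx <- demo_fixture()
    cfg <- pipeline_config(
      genome = fx$paths$genome, gtf = fx$paths$gtf,
      sample_sheet = fx$paths$samples, reads = as.list(fx$paths$reads),
      out_dir = tempfile("circheart_out_"),
      mirna_panel = fx$paths$mirna, mirna_targets = fx$paths$targets,
      gene_counts = fx$paths$gene_counts, seed = 1L)
    .fx_cache$run <- suppressMessages(run_pipeline(cfg))
  }
  .fx_cache$run
}

# small hand-made plus-strand genome with clean GT/AG introns, used by the
# caller and annotator unit tests
toy_genome <- function(seed = 11L, n_exons = 6L, exon_len = 80L,
                       intron_len = 60L, strand = "+", lead = 300L,
                       trail = 300L) {
  set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  exons_t <- replicate(n_exons, rand(exon_len))
  introns_t <- replicate(n_exons - 1L, paste0("GT", rand(intron_len - 4L),
                                              "AG"))
  seg_t <- exons_t[1L]
  for (i in seq_len(n_exons - 1L))
    seg_t <- paste0(seg_t, introns_t[i], exons_t[i + 1L])
  seg <- if (strand == "+") seg_t else circheart::revcomp(seg_t)
  chrom <- paste0(rand(lead), seg, rand(trail))
  Lseg <- nchar(seg)
  starts_t <- cumsum(c(0L, rep(exon_len + intron_len, n_exons - 1L)))
  t_iv <- cbind(starts_t, starts_t + exon_len)
  g_iv <- if (strand == "+") t_iv + lead
          else cbind(Lseg - t_iv[, 2L], Lseg - t_iv[, 1L]) + lead
  g <- gene_model("tg1", "chrT", strand, g_iv,
                  cds = g_iv[2:(n_exons - 1L), , drop = FALSE])
  genome_bundle(c(chrT = chrom), list(g))
}

# a read crossing the back-splice of a circle over exons a..d of gene g
toy_junction_read <- function(genome, gene_id = "tg1", a = 2L, d = 5L,
                              donor_bases = 50L, read_len = 100L) {
  g <- genome$genes[[gene_id]]
  seqs <- vapply(a:d, function(i) {
    e <- g$exons[i, ]                      # transcription order rows
    s <- substr(genome$sequences[[g$chrom]], e[[1L]] + 1L, e[[2L]])
    if (g$strand == "-") circheart::revcomp(s) else s
  }, character(1))
  circ <- paste(seqs, collapse = "")
  L <- nchar(circ)
  p <- L - donor_bases
  substr(paste0(circ, circ), p + 1L, p + read_len)
}
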