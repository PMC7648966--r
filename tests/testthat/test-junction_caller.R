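test_that("anchor index enumerates both strands and flags non-unique k-mers", {
  gb <- genome_bundle(c(c1 = "ACGTACGT"))
  idx <- build_anchor_index(gb, k = 4L)
  occ <- anchor_lookup(idx, "ACGT")
  # plus-strand positions 0 and 4, and the same on minus (own revcomp)
  expect_identical(nrow(occ), 4L)
  expect_setequal(occ$pos[occ$strand == "+"], c(0L, 4L))
  expect_identical(nrow(anchor_lookup(idx, "AAAA")), 0L)
  expect_error(build_anchor_index(gb, k = 9L), "shortest chromosome")
})

test_that("anchor lookup equals a brute-force substring scan", {
  set.seed(42)
  gb <- genome_bundle(c(c1 = random_dna(600), c2 = random_dna(400)))
  idx <- build_anchor_index(gb, k = 8L)
  # brute force: every window of every chromosome, both orientations
  windows <- unlist(lapply(gb$sequences, function(s)
    substring(s, 1:(nchar(s) - 7L), 8:nchar(s))), use.names = FALSE)
  windows_rc <- revcomp(windows)
  brute <- function(km) sum(windows == km) + sum(windows_rc == km)
  kms <- c(vapply(1:80, function(i) random_dna(8L), character(1)),
           substring(gb$sequences[["c1"]], 1:20, 8:27))
  for (km in kms)
    expect_identical(nrow(anchor_lookup(idx, km)), brute(km), info = km)
})

test_that("toy aligner maps contiguous and spliced reads, not junction reads", {
  gb <- toy_genome()
  idx <- build_anchor_index(gb, k = 20L)
  chrom <- gb$sequences[["chrT"]]
  genomic <- substr(chrom, 101L, 200L)
  g <- gb$genes[["tg1"]]
  tx <- gene_cdna(g, gb$sequences)
  spliced <- substr(tx, 41L, 140L)            # crosses exon1|exon2 boundary
  jread <- toy_junction_read(gb)
  reads <- setNames(c(genomic, spliced, jread), c("g", "s", "j"))
  al <- align_linear(reads, idx, gb)
  expect_identical(al$mapped_count, 2L)
  expect_identical(names(al$unmapped), "j")
  # reverse-complement reads also map
  al2 <- align_linear(setNames(revcomp(genomic), "rc"), idx, gb)
  expect_identical(al2$mapped_count, 1L)
})

test_that("a single mismatch is tolerated at mm = 1 but not mm = 0", {
  gb <- toy_genome()
  idx <- build_anchor_index(gb, k = 20L)
  read <- substr(gb$sequences[["chrT"]], 101L, 200L)
  substr(read, 50L, 50L) <- if (substr(read, 50L, 50L) == "A") "C" else "A"
  expect_identical(align_linear(c(r = read), idx, gb, mm = 0L)$mapped_count,
                   0L)
  expect_identical(align_linear(c(r = read), idx, gb, mm = 1L)$mapped_count,
                   1L)
})

test_that("back-splice calls land on annotated exon boundaries", {
  for (strand in c("+", "-")) {
    gb <- toy_genome(seed = 7L, strand = strand)
    idx <- build_anchor_index(gb, k = 20L)
    g <- gb$genes[["tg1"]]
    read <- toy_junction_read(gb, a = 2L, d = 5L)
    cc <- call_backsplice(c(j1 = read), idx, gb)
    expect_identical(nrow(cc), 1L)
    expect_identical(cc$strand, strand)
    if (strand == "+") {
      expect_identical(cc$start, unname(g$exons[2L, 1L]))
      expect_identical(cc$end, unname(g$exons[5L, 2L]))
    } else {
      expect_identical(cc$start, unname(g$exons[5L, 1L]))
      expect_identical(cc$end, unname(g$exons[2L, 2L]))
    }
  }
})

test_that("forward-orientation and non-unique anchors yield no call", {
  gb <- toy_genome(seed = 9L)
  idx <- build_anchor_index(gb, k = 20L)
  g <- gb$genes[["tg1"]]
  chrom <- gb$sequences[["chrT"]]
  # linear spliced read across an ordinary splice junction: anchors place in
  # forward order
  tx <- gene_cdna(g, gb$sequences)
  fwd <- substr(tx, 41L, 140L)
  cc <- call_backsplice(c(f = fwd), idx, gb)
  expect_identical(nrow(cc), 0L)
  expect_identical(attr(cc, "log")[["forward_orientation"]], 1L)
  # duplicating the acceptor anchor region elsewhere kills uniqueness
  jread <- toy_junction_read(gb)
  dup <- paste0(chrom, substr(jread, 81L, 100L))
  gb2 <- genome_bundle(c(chrT = dup), gb$genes)
  idx2 <- build_anchor_index(gb2, k = 20L)
  cc2 <- call_backsplice(c(j = jread), idx2, gb2)
  expect_identical(nrow(cc2), 0L)
  expect_identical(attr(cc2, "log")[["anchor_nonunique"]], 1L)
})

test_that("larger anchors never produce more candidate calls", {
  gb <- toy_genome(seed = 13L)
  reads <- setNames(
    vapply(25:45, function(d) toy_junction_read(gb, donor_bases = d),
           character(1)),
    sprintf("r%d", 25:45))
  n_calls <- vapply(c(20L, 25L, 30L), function(k) {
    idx <- build_anchor_index(gb, k = k)
    nrow(call_backsplice(reads, idx, gb))
  }, integer(1))
  expect_true(all(diff(n_calls) <= 0L))
})

test_that("aggregation collapses duplicate reads and applies the detection rule", {
  mk <- function(read_id, sample, seq)
    data.frame(read_id = read_id, chrom = "c", start = 10L, end = 90L,
               strand = "+", read_seq = seq, sample = sample,
               stringsAsFactors = FALSE)
  calls <- rbind(mk("r1", "s1", "AAA"), mk("r2", "s1", "CCC"),
                 mk("r3", "s1", "GGG"), mk("r4", "s1", "AAA"))
  agg <- aggregate_junctions(calls, sample_ids = c("s1", "s2"))
  expect_identical(unname(agg$support[1L, ]), c(3L, 0L))
  # one read per sample everywhere: dropped
  singles <- rbind(mk("a", "s1", "AAA"), mk("b", "s2", "CCC"))
  expect_identical(nrow(aggregate_junctions(singles)$table), 0L)
  # support exactly 2 in one sample: kept (boundary of the detection rule)
  pair <- rbind(mk("a", "s1", "AAA"), mk("b", "s1", "CCC"))
  expect_identical(nrow(aggregate_junctions(pair)$table), 1L)
})

test_that("fixture junctions are recovered with signal-consistent strands", {
  run <- demo_pipeline()
  fx <- demo_fixture()
  ev <- evaluate_junctions(run$junctions, fx$truth$circ)
  expect_identical(ev$recall, 1)
  expect_identical(ev$precision, 1)
  # splice signal matches the reported strand for every call
  tab <- run$junctions$table
  chrom <- fx$genome$sequences[["chr1"]]
  sigL <- substring(chrom, tab$start - 1L, tab$start)
  sigR <- substring(chrom, tab$end + 1L, tab$end + 2L)
  expect_true(all(ifelse(tab$strand == "+", sigL == "AG" & sigR == "GT",
                         sigL == "AC" & sigR == "CT")))
  # mapped totals equal the truth bookkeeping
  st <- fx$truth$samples
  expect_identical(unname(run$mapped_totals[st$sample_id]),
                   st$n_mapped_expected)
})
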