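test_that("genome generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$genes, g2$genes)
})

test_that("every annotated intron carries GT/AG on the gene strand", {
  fx <- demo_fixture()
  for (g in fx$genome$genes) {
    ex <- g$exons[order(g$exons[, 1L]), , drop = FALSE]
    chrom <- fx$genome$sequences[[g$chrom]]
    for (i in seq_len(nrow(ex) - 1L)) {
      don <- substr(chrom, ex[i, 2L] + 1L, ex[i, 2L] + 2L)
      acc <- substr(chrom, ex[i + 1L, 1L] - 1L, ex[i + 1L, 1L])
      if (g$strand == "+") {
        expect_identical(don, "GT", info = g$gene_id)
        expect_identical(acc, "AG", info = g$gene_id)
      } else {
        expect_identical(don, "CT", info = g$gene_id)
        expect_identical(acc, "AC", info = g$gene_id)
      }
    }
  }
})

test_that("trap pairs are homologous and rt pairs are not", {
  fx <- demo_fixture()
  ident <- function(a, b) {
    ca <- strsplit(a, "")[[1L]]
    cb <- strsplit(b, "")[[1L]]
    n <- min(length(ca), length(cb))
    mean(ca[seq_len(n)] == cb[seq_len(n)])
  }
  for (p in 1:5) {
    tp <- ident(gene_cdna(fx$genome$genes[[sprintf("tp%dA", p)]],
                          fx$genome$sequences),
                gene_cdna(fx$genome$genes[[sprintf("tp%dB", p)]],
                          fx$genome$sequences))
    expect_gte(tp, 0.9)
    expect_lte(abs(tp - 0.95), 0.03)
  }
  rt <- ident(gene_cdna(fx$genome$genes[["rt1A"]], fx$genome$sequences),
              gene_cdna(fx$genome$genes[["rt1B"]], fx$genome$sequences))
  expect_lte(rt, 0.5)
})

test_that("planted circles respect their construction invariants", {
  fx <- demo_fixture()
  tr <- fx$truth$circ
  expect_identical(nrow(tr), 60L)
  expect_identical(anyDuplicated(junction_key(tr)), 0L)
  expect_true(all(tr$start < tr$end))
  # spliced length equals the sum of constituent exon lengths
  exonic <- tr[tr$exon_composition != "", ]
  for (i in seq_len(nrow(exonic))) {
    comp <- circheart:::parse_composition(exonic$exon_composition[i])
    lens <- vapply(seq_along(comp$gene), function(j) {
      e <- fx$genome$genes[[comp$gene[j]]]$exons[comp$idx[j], ]
      e[[2L]] - e[[1L]]
    }, numeric(1))
    expect_identical(exonic$spliced_len[i], as.integer(sum(lens)))
  }
  # rt topology: acceptor exon 4 of the upstream gene
  rt <- tr[tr$rt_status == "true_rt", ]
  expect_true(all(rt$acceptor_exon == 4L))
  expect_true(all(rt$origin == "two-gene"))
  expect_identical(sum(tr$rt_status == "homology_artifact"), 10L)
})

test_that("per-sample planted support equals generated junction reads", {
  fx <- demo_fixture()
  tr <- fx$truth$circ
  for (s in fx$truth$samples$sample_id) {
    ids <- names(fx$reads[[s]])
    bsj <- ids[grepl(":bsj:", ids) & !endsWith(ids, ":dup")]
    got <- table(sub(".*:bsj:(t[0-9]+):.*", "\\1", bsj))
    want <- setNames(tr[[paste0("support.", s)]], tr$truth_id)
    expect_identical(as.integer(want[names(got)]), as.integer(got))
    expect_identical(sum(want), sum(got))
    # junction reads are distinct sequences within each sample
    seqs <- fx$reads[[s]][bsj]
    expect_identical(anyDuplicated(seqs), 0L)
  }
})

test_that("read simulation is deterministic and counts reconcile", {
  fx <- demo_fixture()
  cfg <- fx$config
  r2 <- simulate_reads(fx$genome, fx$truth, cfg)
  expect_identical(r2$reads, fx$reads)
  st <- fx$truth$samples
  expect_true(all(st$n_reads >= st$n_mapped_expected))
  lin <- vapply(fx$reads, function(r) sum(grepl(":lin:", names(r))),
                integer(1))
  gc <- colSums(as.matrix(
    fx$truth$gene[, paste0("count.", st$sample_id)]))
  expect_identical(unname(lin), unname(as.integer(gc)))
})

test_that("planted miRNA site truth includes the junction-spanning site", {
  fx <- demo_fixture()
  s <- fx$sites
  planted <- s[s$n_8mer + s$n_7mer_m8 + s$n_7mer_a1 > 0, ]
  expect_identical(sum(planted$n_junction_spanning), 1L)
  # top-tier circle carries >= 10 counted sites for one miRNA
  tot <- planted$n_8mer + planted$n_7mer_m8 + planted$n_7mer_a1
  expect_gte(max(tot), 10L)
  # and one planted pair sits exactly at the candidate boundary
  expect_true(5L %in% tot)
})

test_that("an explicit chrom_length smaller than the layout errors", {
  expect_error(generate_genome(sim_config(seed = 3, chrom_length = 1000L)),
               "too small")
})

test_that("NB count simulation is deterministic with planted effects", {
  a <- simulate_nb_counts(100, 5, mu = 20, phi = 0.1, n_de = 10, lfc = 2,
                          seed = 3)
  b <- simulate_nb_counts(100, 5, mu = 20, phi = 0.1, n_de = 10, lfc = 2,
                          seed = 3)
  expect_identical(a$counts, b$counts)
  expect_identical(dim(a$counts), c(100L, 10L))
  de <- rowMeans(a$counts[1:10, 6:10])
  nu <- rowMeans(a$counts[1:10, 1:5])
  expect_gt(mean(de) / mean(nu), 2)
})
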