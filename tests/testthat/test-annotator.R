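test_that("single-gene origins follow the CDS coverage of the junction span", {
  gb <- toy_genome(seed = 21L)        # CDS = exons 2..5 (of 6), full exons
  g <- gb$genes[["tg1"]]
  j <- data.frame(chrom = "chrT", start = g$exons[2L, 1L],
                  end = g$exons[4L, 2L], strand = "+")
  oc <- assign_origin(j, gb$genes)
  expect_identical(oc$origin, "CDS")
  expect_identical(oc$acceptor_exon, 2L)
  expect_identical(oc$donor_exon, 4L)
  expect_true(oc$boundary_exact)
  # span from exon 1 (non-CDS) through exon 3 mixes UTR and CDS
  j2 <- data.frame(chrom = "chrT", start = g$exons[1L, 1L],
                   end = g$exons[3L, 2L], strand = "+")
  expect_identical(assign_origin(j2, gb$genes)$origin, "UTR-CDS")
  # both ends inside intron 1
  j3 <- data.frame(chrom = "chrT", start = g$exons[1L, 2L] + 5L,
                   end = g$exons[2L, 1L] - 5L, strand = "+")
  expect_identical(assign_origin(j3, gb$genes)$origin, "intronic")
  # both ends outside any gene span
  j4 <- data.frame(chrom = "chrT", start = 5L, end = 100L, strand = "+")
  expect_identical(assign_origin(j4, gb$genes)$origin, "intergenic")
  expect_error(assign_origin(data.frame(chrom = "chrX", start = 1L,
                                        end = 5L, strand = "+"), gb$genes),
               "absent")
})

test_that("two-gene origin requires same strand, adjacency and upstream order", {
  fx <- demo_fixture()
  tr <- fx$truth$circ
  two <- tr[tr$origin == "two-gene", ][1L, ]
  oc <- assign_origin(two, fx$genome$genes)
  expect_identical(oc$origin, "two-gene")
  expect_identical(oc$host1, two$host1)
  expect_identical(oc$host2, two$host2)
  expect_identical(oc$acceptor_exon, 4L)
})

test_that("spliced sequences concatenate exons on the transcribed strand", {
  chrom <- paste0("AAAA", "GT", strrep("T", 10), "AG", "GGG", "GT",
                  strrep("C", 10), "AG", "CCCC")
  ex <- matrix(c(0L, 4L, 18L, 21L, 35L, 39L), 3L, byrow = TRUE)
  gp <- gene_model("p", "c", "+", ex)
  gb <- genome_bundle(c(c = chrom), list(gp))
  j <- data.frame(chrom = "c", start = 0L, end = 39L, strand = "+")
  oc <- assign_origin(j, gb$genes)
  sp <- splice_circ_sequence(j, oc, gb)
  expect_identical(sp$seq, "AAAAGGGCCCC")
  # minus-strand gene: reverse complement, transcription order
  gm <- gene_model("m", "c", "-", ex[3:1, , drop = FALSE])
  gbm <- genome_bundle(c(c = chrom), list(gm))
  ocm <- assign_origin(j2 <- data.frame(chrom = "c", start = 0L, end = 39L,
                                        strand = "-"), gbm$genes)
  spm <- splice_circ_sequence(j2, ocm, gbm)
  expect_identical(spm$seq, revcomp("AAAAGGGCCCC"))
  # non-boundary junction falls back to the genomic span
  j3 <- data.frame(chrom = "c", start = 2L, end = 20L, strand = "+")
  oc3 <- assign_origin(j3, gb$genes)
  expect_false(oc3$boundary_exact)
  expect_identical(splice_circ_sequence(j3, oc3, gb)$seq,
                   substr(chrom, 3L, 20L))
})

test_that("names rank single-gene circles by coordinates and encode rt exons", {
  rec <- data.frame(
    chrom = "c", start = c(50L, 10L, 100L), end = c(80L, 90L, 200L),
    strand = "+", origin = c("CDS", "CDS", "two-gene"),
    host1 = c("gA", "gA", "up"), host2 = c(NA, NA, "dn"),
    acceptor_exon = c(2L, 1L, 4L), donor_exon = c(3L, 4L, 2L),
    stringsAsFactors = FALSE)
  nm <- name_circrna(rec)
  expect_identical(nm, c("circgA_2", "circgA_1", "up_e4:dn_e2"))
  rec$host1 <- NA_character_
  rec$origin <- "intergenic"
  expect_identical(name_circrna(rec)[2L], "circINTERGENIC_c_10")
})

test_that("fixture annotation matches truth origins, hosts and sequences", {
  run <- demo_pipeline()
  fx <- demo_fixture()
  rec <- run$records
  tr <- fx$truth$circ
  m <- match(junction_key(rec), junction_key(tr))
  expect_false(anyNA(m))
  expect_identical(rec$origin, tr$origin[m])
  expect_identical(rec$host1[!is.na(rec$host1)],
                   tr$host1[m][!is.na(tr$host1[m])])
  expect_identical(rec$spliced_seq, tr$spliced_seq[m])
  # origin classes partition the record set
  expect_identical(sum(table(rec$origin)), nrow(rec))
  # naming is a bijection
  expect_identical(anyDuplicated(rec$name), 0L)
  # two-gene names follow the acceptor:donor exon pattern
  two <- rec[rec$origin == "two-gene", ]
  expect_true(all(grepl("^(rt|tp)[0-9]+A_e4:(rt|tp)[0-9]+B_e[12]$",
                        two$name)))
})

test_that("feature statistics match a brute-force recount on the fixture", {
  run <- demo_pipeline()
  fx <- demo_fixture()
  st <- feature_stats(run$records, fx$genome$genes)
  rec <- run$records
  # per-gene distribution equals a direct table of host counts
  direct <- table(table(rec$host1[!is.na(rec$host1)]))
  expect_identical(as.integer(st$per_gene$Freq),
                   as.integer(direct[st$per_gene$n_circ]))
  # acceptor-exon distribution mass
  acc <- table(rec$acceptor_exon[rec$boundary_exact])
  expect_identical(as.integer(st$acceptor_exon$Freq),
                   as.integer(acc[st$acceptor_exon$exon]))
  # mean circRNAs per gene binned by gene exon count, recomputed directly
  ng <- vapply(fx$genome$genes, function(g) nrow(g$exons), integer(1))
  cnt <- vapply(names(fx$genome$genes), function(g)
    sum(rec$host1 == g, na.rm = TRUE), integer(1))
  expect_identical(st$by_gene_exons$mean_circ[1L],
                   mean(cnt[ng <= 10L]))
  expect_identical(st$by_gene_exons$n_genes[1L], sum(ng <= 10L))
})
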