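test_that("flank extraction follows the definition and the split rule", {
  set.seed(31)
  s200 <- random_dna(200L)
  fl <- extract_flanks(s200, w = 50L)
  expect_identical(fl$acceptor_flank, substr(s200, 1L, 50L))
  expect_identical(fl$donor_flank, substr(s200, 151L, 200L))
  s60 <- random_dna(60L)
  fl60 <- extract_flanks(s60, w = 50L)
  expect_identical(nchar(fl60$acceptor_flank), 30L)
  expect_identical(nchar(fl60$donor_flank), 30L)
  expect_identical(paste0(fl60$acceptor_flank, fl60$donor_flank), s60)
  expect_error(extract_flanks("", 50L), "empty")
})

test_that("self-alignment and orientation symmetry behave exactly", {
  set.seed(32)
  q <- random_dna(50L)
  al <- local_align(q, q)
  expect_identical(al$score, 50L)
  expect_identical(al$identity, 1)
  expect_identical(al$length, 50L)
  expect_true(al$hit)
  alr <- local_align(revcomp(q), q)
  expect_identical(alr$score, 50L)
  expect_identical(alr$orientation, "-")
})

test_that("ten evenly spaced substitutions give a full-length 0.8-identity hit", {
  set.seed(33)
  q <- random_dna(50L)
  mut <- q
  for (p in seq(3L, 48L, by = 5L)) {
    cur <- substr(mut, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  }
  al <- local_align(mut, q)
  # full-length alignment scores 40 - 20 = 20; terminal trims are at best
  # score-neutral, so the optimal score is exact while the reported span may
  # shed score-neutral edge mismatches
  expect_identical(al$score, as.integer(oracle_sw_best(mut, q)))
  expect_gte(al$identity, 0.8)
  expect_gte(al$length, 25L)
  expect_true(al$hit)
})

test_that("alignment scores agree with the DP oracle and Biostrings", {
  set.seed(34)
  for (i in 1:40) {
    q <- random_dna(sample(10:60, 1L))
    s <- random_dna(sample(10:60, 1L))
    al <- local_align(q, s)
    expect_identical(al$score, as.integer(oracle_sw_best(q, s)),
                     info = paste(q, s))
  }
  # independent cross-check against Biostrings pairwiseAlignment (same gap
  # convention: opening charged once plus extension per gap position)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in 1:15) {
    q <- random_dna(40L)
    s <- random_dna(200L)
    bs <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    fwd <- circheart:::`.sw_align`(q, s, 1L, -2L, 5L, 2L)
    expect_identical(fwd[["score"]], as.integer(Biostrings::score(bs)))
  }
})

test_that("the decision rule separates rt circles from homology artifacts", {
  fx <- demo_fixture()
  gb <- fx$genome
  tr <- fx$truth$circ
  run_one <- function(row) {
    fl <- extract_flanks(row$spliced_seq)
    suppressWarnings(classify_two_gene(
      fl, gene_cdna(gb$genes[[row$host1]], gb$sequences),
      gene_cdna(gb$genes[[row$host2]], gb$sequences)))
  }
  rt_row <- tr[tr$rt_status == "true_rt", ][1L, ]
  expect_identical(run_one(rt_row)$call, "true_rt")
  trap_row <- tr[tr$rt_status == "homology_artifact", ][1L, ]
  expect_identical(run_one(trap_row)$call, "homology_artifact")
  # limiting case: downstream gene an exact copy of the upstream gene
  fl <- extract_flanks(rt_row$spliced_seq)
  cd1 <- gene_cdna(gb$genes[[rt_row$host1]], gb$sequences)
  expect_identical(classify_two_gene(fl, cd1, cd1)$call,
                   "homology_artifact")
  expect_error(classify_two_gene(fl, character(0), cd1), "missing cDNA")
})

test_that("relaxing hit thresholds only moves calls toward artifact", {
  fx <- demo_fixture()
  run <- demo_pipeline()
  strict <- screen_rt(run$records, fx$genome, min_identity = 0.8,
                      min_length = 25L)
  relaxed <- suppressWarnings(screen_rt(run$records, fx$genome,
                                        min_identity = 0.5,
                                        min_length = 15L))
  flipped <- strict$call == "true_rt" & relaxed$call == "homology_artifact"
  reverse <- strict$call == "homology_artifact" & relaxed$call == "true_rt"
  expect_false(any(reverse))
  # degenerate endpoint: with no thresholds every flank hits both genes
  zero <- suppressWarnings(screen_rt(run$records, fx$genome,
                                     min_identity = 0, min_length = 0L))
  expect_true(all(zero$call == "homology_artifact"))
})

test_that("classification is invariant to transcript order within a gene", {
  fx <- demo_fixture()
  tr <- fx$truth$circ
  row <- tr[tr$rt_status == "true_rt", ][2L, ]
  fl <- extract_flanks(row$spliced_seq)
  cd1 <- gene_cdna(fx$genome$genes[[row$host1]], fx$genome$sequences)
  cd2 <- gene_cdna(fx$genome$genes[[row$host2]], fx$genome$sequences)
  extra <- substr(cd1, 10L, 80L)
  a <- classify_two_gene(fl, c(cd1, extra), cd2)
  b <- classify_two_gene(fl, c(extra, cd1), cd2)
  expect_identical(a$call, b$call)
})

test_that("all twenty planted two-gene circles are classified correctly", {
  fx <- demo_fixture()
  run <- demo_pipeline()
  ev <- evaluate_rt(run$rt, fx$truth$circ)
  expect_identical(ev$n, 20L)
  expect_identical(ev$n_correct, 20L)
})
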