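toy_mirna <- function(seed7) {
  # mature miRNA whose positions 2-8 equal seed7
  paste0("A", seed7, "GCAUGCAUGCAUGC")
}

test_that("the circular scan string wraps at most 7 nt", {
  expect_identical(circular_scan_sequence("AAACCC"), "AAACCCAAACCC")
  s <- random_rna(20L)
  expect_identical(nchar(circular_scan_sequence(s)), 27L)
  expect_identical(circular_scan_sequence(s),
                   paste0(s, substr(s, 1, 7)))
})

test_that("site types and precedence match the canonical definitions", {
  m <- toy_mirna("AGCAGCA")          # S = UGCUGCU
  hits <- seed_sites("AAUGCUGCUCC", m)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 2L)
  expect_identical(hits$type, "7mer-m8")
  # an A after the heptamer upgrades it to an 8mer (not also a 7mer)
  hits8 <- seed_sites("CCUGCUGCUACC", m)
  expect_identical(hits8$type[hits8$start == 2L], "8mer")
  expect_false(any(hits8$type == "7mer-m8" & hits8$start == 2L))
  # 7mer-A1: positions 7..2 plus A, without the m8 match
  hits7a1 <- seed_sites("CCGCUGCUACC", m)
  expect_identical(hits7a1$type[hits7a1$start == 2L], "7mer-A1")
  # poly-A target has no site for a GC seed
  expect_identical(nrow(seed_sites(strrep("A", 100), m)), 0L)
  # 6mer only counted on request
  expect_identical(nrow(seed_sites("CCGCUGCUCCC", m)), 0L)
  expect_identical(seed_sites("CCGCUGCUCCC", m, include_6mer = TRUE)$type,
                   "6mer")
  expect_error(seed_sites("ACGU", paste0("A", "AXCGUAU", "AAAA")),
               "non-ACGU")
})

test_that("junction-wrapping sites are found and counting is rotation-invariant", {
  m <- toy_mirna("AGCAGCA")          # S = UGCUGCU
  # wraps to UGCU|GCU; the C guard keeps the wrapped site a 7mer-m8
  s <- paste0("GCU", "C", random_rna(79L), "UGCU")
  # ensure no accidental site in the random interior
  hits <- seed_sites(s, m)
  wrap <- hits[hits$start == nchar(s) - 4L, ]
  expect_identical(nrow(wrap), 1L)
  expect_identical(wrap$type, "7mer-m8")
  rot <- function(x, k) {
    k <- k %% nchar(x)
    paste0(substr(x, k + 1L, nchar(x)), substr(x, 1L, k))
  }
  base_counts <- table(seed_sites(s, m)$type)
  for (k in c(1L, 7L, 40L, nchar(s) - 2L))
    expect_identical(table(seed_sites(rot(s, k), m)$type), base_counts)
})

test_that("seed_sites equals the brute-force oracle on random circles", {
  set.seed(41)
  panel <- vapply(1:10, function(i) random_rna(22L), character(1))
  for (i in 1:150) {
    s <- random_rna(500L)
    m <- panel[[(i - 1L) %% 10L + 1L]]
    got <- seed_sites(s, m, include_6mer = (i %% 2 == 0))
    want <- oracle_seed_sites(s, m, include_6mer = (i %% 2 == 0))
    expect_identical(got, want, info = i)
  }
})

test_that("candidate and top tiers apply the 5- and 10-site thresholds", {
  st <- data.frame(circ_id = c("a", "a", "b", "c"),
                   mirna_id = c("m1", "m2", "m1", "m2"),
                   n_sites = c(5L, 2L, 4L, 12L), stringsAsFactors = FALSE)
  sc <- sponge_candidates(st)
  expect_setequal(sc$candidate_ids, c("a", "c"))
  expect_identical(sc$top_ids, "c")
  expect_identical(sc$matrix["b", "m1"], 4L)
  expect_identical(nrow(sponge_candidates(st, min_sites = 13L)$candidates),
                   0L)
})

test_that("network edges count out and unknown miRNAs are skipped", {
  cand <- data.frame(circ_id = "C", mirna_id = "m1", n_sites = 6L,
                     stringsAsFactors = FALSE)
  targets <- data.frame(mirna_id = c("m1", "m1", "mX"),
                        gene_id = c("g1", "g2", "g3"),
                        stringsAsFactors = FALSE)
  panel <- data.frame(mirna_id = "m1", mature = random_rna(22L),
                      stringsAsFactors = FALSE)
  expect_warning(net <- build_network(cand, targets, panel = panel),
                 "unknown miRNA")
  expect_identical(nrow(net$edges), 3L)
  expect_identical(sum(net$edges$interaction == "circ-miR"), 1L)
  empty <- build_network(cand[0, ], targets[0, ], panel = panel)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("fixture site counts, tiers and network match the planted truth", {
  run <- demo_pipeline()
  fx <- demo_fixture()
  ev <- evaluate_sites(run$sites, fx$sites, run$records, fx$truth$circ)
  expect_identical(ev$agreement, 1)
  # planted tier structure: one top-tier circle, one boundary candidate
  expect_true(any(run$sponge$candidates$n_sites >= 10L))
  expect_true(5L %in% run$sponge$candidates$n_sites)
  # network edges reconstruct from candidates and target lists
  n_targets <- nrow(fx$targets)
  expect_identical(nrow(run$network$edges),
                   nrow(run$sponge$candidates) + n_targets)
  # released-repression summary only lists down/down pairs
  rel <- run$network$released_targets
  if (nrow(rel)) {
    expect_true(all(run$gene_de$direction[match(rel$gene_id,
                                                run$gene_de$feature_id)] ==
                      "down"))
  }
})
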