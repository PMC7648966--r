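test_that("dispersion estimation recovers Poisson and NB regimes", {
  cm0 <- simulate_nb_counts(2000, 5, mu = 20, phi = 0, seed = 11)
  expect_lte(estimate_dispersion(cm0)$phi, 0.01)
  cm1 <- simulate_nb_counts(2000, 5, mu = 20, phi = 0.1, seed = 12)
  phi <- estimate_dispersion(cm1)$phi
  expect_gte(phi, 0.05)
  expect_lte(phi, 0.2)
  # identical counts across samples: floored at 1e-6
  cmc <- count_matrix(matrix(5L, 3, 4, dimnames = list(letters[1:3],
                                                       LETTERS[1:4])),
                      setNames(rep(1e6, 4), LETTERS[1:4]),
                      setNames(rep(c("A", "B"), 2), LETTERS[1:4]))
  expect_identical(estimate_dispersion(cmc)$phi, 1e-6)
})

test_that("the exact test matches binomial and symmetry oracles", {
  # balanced counts, equal group sizes: the observed split is modal
  expect_identical(nb_exact_test(c(5, 5, 5), c(5, 5, 5), 0.1), 1)
  # phi = 0, 5 vs 5, split 0 vs 10: two-sided binomial tail
  p <- nb_exact_test(c(0, 0, 0, 0, 0), c(2, 2, 2, 2, 2), 0)
  expect_equal(p, 2 * dbinom(0, 10, 0.5), tolerance = 1e-12)
  # group swap leaves the p-value unchanged
  set.seed(13)
  a <- rpois(5, 20); b <- rpois(5, 35)
  expect_equal(nb_exact_test(a, b, 0.1), nb_exact_test(b, a, 0.1))
  # zero total
  expect_identical(nb_exact_test(c(0, 0), c(0, 0), 0.1), 1)
  expect_error(nb_exact_test(c(-1, 0), c(0, 0), 0.1), "negative")
})

test_that("the exact test agrees with edgeR at equal library sizes", {
  skip_if_not_installed("edgeR")
  cm <- simulate_nb_counts(500, 5, mu = 20, phi = 0.1, seed = 7)
  mine <- vapply(seq_len(500), function(i)
    nb_exact_test(cm$counts[i, 1:5], cm$counts[i, 6:10], 0.1), numeric(1))
  dge <- edgeR::DGEList(counts = cm$counts, group = cm$groups,
                        lib.size = rep(1e6, 10))
  theirs <- edgeR::exactTest(dge, dispersion = 0.1)$table$PValue
  expect_equal(mine, theirs, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # raising one p never lowers any FDR
  p <- runif(20)
  q1 <- bh_adjust(p)
  p2 <- p; p2[7] <- min(1, p2[7] + 0.3)
  expect_true(all(bh_adjust(p2) >= q1 - 1e-12))
})

test_that("de_test applies the conjunction rule and label symmetry", {
  cm <- simulate_nb_counts(300, 5, mu = 30, phi = 0.05, n_de = 30, lfc = 2,
                           seed = 15)
  de <- de_circ(cm, ref = "A")
  expect_true(all(de$fdr >= de$pvalue - 1e-12))
  expect_gte(mean(de$direction[1:30] == "up"), 0.9)
  # swapping groups negates the log2 fold change exactly
  cm_sw <- count_matrix(cm$counts, setNames(cm$totals, colnames(cm$counts)),
                        setNames(ifelse(cm$groups == "A", "B", "A"),
                                 colnames(cm$counts)))
  de_sw <- de_circ(cm_sw, ref = "B", phi = attr(de, "dispersion")$phi)
  expect_equal(de_sw$log2fc, de$log2fc)
  de_sw2 <- de_circ(cm_sw, ref = "A", phi = attr(de, "dispersion")$phi)
  expect_equal(de_sw2$log2fc, -de$log2fc)
  # a feature can be fold-changed yet non-significant at low counts:
  # split 1 vs 6 has two-sided binomial p = 0.125 but FC > 2
  low <- matrix(c(1L, 0L, 0L, 0L, 0L, 2L, 2L, 1L, 1L, 0L), 1)
  dimnames(low) <- list("f", sprintf("s%d", 1:10))
  cml <- count_matrix(low, setNames(rep(1e6, 10), colnames(low)),
                      setNames(rep(c("A", "B"), each = 5), colnames(low)))
  del <- de_circ(cml, ref = "A", phi = 1e-6)
  expect_identical(del$direction, "ns")
  expect_gt(abs(del$log2fc), 1)
})

test_that("gene-track significance is gated on FDR, circRNAs on raw p", {
  cm <- simulate_nb_counts(400, 5, mu = 25, phi = 0.1, n_de = 5, lfc = 2,
                           seed = 16)
  dc <- de_circ(cm, ref = "A")
  dg <- de_genes(cm, ref = "A", phi = attr(dc, "dispersion")$phi)
  # FDR gating can only lose significant calls relative to raw-p gating
  expect_true(all(which(dg$direction != "ns") %in%
                    which(dc$direction != "ns")))
})
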