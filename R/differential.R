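# Two-group differential expression with a conditional negative-binomial
# exact test under a common dispersion, plus Benjamini-Hochberg adjustment
# for the linear-gene track. Significance mirrors the asymmetric published
# thresholds: raw p < alpha for circRNAs, FDR < alpha for genes (both with
# |FC| > threshold).

#' Method-of-moments common dispersion
#'
#' Counts are scaled to the mean library size; per feature, the within-group
#' pooled variance gives a moment estimate
#' `phi_i = max(0, (s2_i - m_i) / m_i^2)`, and the common dispersion is the
#' median over features with mean at least 1, floored at 1e-6.
#'
#' @param cm a [count_matrix()] with two groups of >= 2 samples.
#' @return list with `phi` (common dispersion) and `method`.
#' @export
estimate_dispersion <- function(cm) {
  grp <- unique(cm$groups)
  if (length(grp) != 2L) stopf("exactly two groups required")
  if (any(table(cm$groups) < 2L)) stopf("need >= 2 samples per group")
  y <- sweep(cm$counts, 2L, mean(cm$totals) / cm$totals, `*`)
  gA <- cm$groups == grp[1L]
  gB <- cm$groups == grp[2L]
  vA <- apply(y[, gA, drop = FALSE], 1L, var)
  vB <- apply(y[, gB, drop = FALSE], 1L, var)
  nA <- sum(gA); nB <- sum(gB)
  s2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
  m <- rowMeans(y)
  use <- m >= 1
  if (!any(use)) stopf("no feature with scaled mean count >= 1")
  phi_i <- pmax(0, (s2[use] - m[use]) / m[use]^2)
  list(phi = max(1e-6, median(phi_i)), method = "pooled moments, median")
}

#' Conditional negative-binomial exact test for one feature
#'
#' Counts are notionally equalised to the common (mean) library size.
#' Conditional on the total `t` of the equalised counts, the probability of
#' every split `(a, t - a)` between the groups is computed under equal group
#' means (group sums are NB with size `n_g / phi`); the two-sided p-value is
#' the total probability of splits no more likely than the observed one.
#' `phi = 0` reduces to the binomial split with proportion
#' `nA / (nA + nB)`. A total of zero gives p = 1.
#'
#' @param countsA,countsB integer count vectors of the two groups.
#' @param phi common NB dispersion (>= 0).
#' @param library_sizes optional per-sample library sizes, ordered as
#'   `c(countsA, countsB)`; `NULL` means equal libraries.
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(countsA, countsB, phi, library_sizes = NULL) {
  if (any(c(countsA, countsB) < 0)) stopf("negative counts")
  if (phi < 0) stopf("negative dispersion")
  if (!is.null(library_sizes)) {
    f <- mean(library_sizes) / library_sizes
    x <- round(c(countsA, countsB) * f)
    countsA <- x[seq_along(countsA)]
    countsB <- x[-seq_along(countsA)]
  }
  nA <- length(countsA); nB <- length(countsB)
  t <- sum(countsA) + sum(countsB)
  if (t == 0) return(1)
  a_obs <- sum(countsA)
  a <- 0:t
  if (phi < 1e-12) {
    probs <- dbinom(a, t, nA / (nA + nB))
  } else {
    mu <- t / (nA + nB)
    probs <- dnbinom(a, size = nA / phi, mu = nA * mu) *
      dnbinom(t - a, size = nB / phi, mu = nB * mu)
  }
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[a_obs + 1L] * (1 + 1e-10)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return FDR values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Two-group differential test over a count matrix
#'
#' Fold changes come from library-size-normalised group means with a
#' pseudocount of 0.5 (fold change only, never the test); p-values from
#' [nb_exact_test()] under the common dispersion of
#' [estimate_dispersion()]; FDR from [bh_adjust()]. The significance rule is
#' `|FC| > fc_threshold` together with raw `p < alpha` (`sig_on =
#' "pvalue"`, the circRNA rule) or `FDR < alpha` (`sig_on = "fdr"`, the
#' linear-gene rule).
#'
#' @param cm a [count_matrix()] (for circRNAs: restricted to the
#'   high-confidence tier first).
#' @param ref reference (control-like) group label; defaults to `"normal"`
#'   if present, else the first group in column order. The log2 fold change
#'   is alt over ref.
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @param sig_on `"pvalue"` or `"fdr"`.
#' @param phi optional fixed dispersion (skips estimation).
#' @return data.frame sorted as input: `feature_id`, `mean_ref`,
#'   `mean_alt`, `log2fc`, `pvalue`, `fdr`, `direction` (up/down/ns);
#'   attribute `dispersion` carries the estimate.
#' @export
de_test <- function(cm, ref = NULL, fc_threshold = 2, alpha = 0.05,
                    sig_on = c("pvalue", "fdr"), phi = NULL) {
  sig_on <- match.arg(sig_on)
  grp <- unique(cm$groups)
  if (length(grp) != 2L) stopf("exactly two groups required")
  ref <- ref %||% if ("normal" %in% grp) "normal" else grp[1L]
  if (!ref %in% grp) stopf("unknown reference group %s", ref)
  alt <- setdiff(grp, ref)
  disp <- if (is.null(phi)) estimate_dispersion(cm)
          else list(phi = phi, method = "fixed")
  selR <- cm$groups == ref
  selA <- cm$groups == alt
  y <- sweep(cm$counts, 2L, mean(cm$totals) / cm$totals, `*`)
  mR <- rowMeans(y[, selR, drop = FALSE])
  mA <- rowMeans(y[, selA, drop = FALSE])
  lfc <- log2((mA + 0.5) / (mR + 0.5))
  pv <- vapply(seq_len(nrow(cm$counts)), function(i)
    nb_exact_test(cm$counts[i, selR], cm$counts[i, selA], disp$phi,
                  library_sizes = c(cm$totals[selR], cm$totals[selA])),
    numeric(1))
  fdr <- bh_adjust(pv)
  crit <- if (sig_on == "pvalue") pv < alpha else fdr < alpha
  direction <- ifelse(crit & lfc > log2(fc_threshold), "up",
                      ifelse(crit & lfc < -log2(fc_threshold), "down", "ns"))
  res <- data.frame(feature_id = rownames(cm$counts), mean_ref = mR,
                    mean_alt = mA, log2fc = lfc, pvalue = pv, fdr = fdr,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "dispersion") <- disp
  res
}

#' @rdname de_test
#' @export
de_circ <- function(cm, ref = NULL, fc_threshold = 2, alpha = 0.05,
                    phi = NULL)
  de_test(cm, ref, fc_threshold, alpha, sig_on = "pvalue", phi = phi)

#' @rdname de_test
#' @export
de_genes <- function(cm, ref = NULL, fc_threshold = 2, alpha = 0.05,
                     phi = NULL)
  de_test(cm, ref, fc_threshold, alpha, sig_on = "fdr", phi = phi)
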