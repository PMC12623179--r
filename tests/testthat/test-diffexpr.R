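test_that("paired fold change is the geometric mean of per-line ratios", {
  treated <- matrix(20, 1, 5, dimnames = list("g1", paste0("L", 1:5)))
  control <- matrix(10, 1, 5, dimnames = list("g1", paste0("L", 1:5)))
  pf <- paired_fold_change(treated, control)
  expect_equal(unname(pf$fc), 2)
  expect_equal(unname(pf$ln_ratio), log(2), tolerance = 1e-12)

  same <- paired_fold_change(control, control)
  expect_equal(unname(same$fc), 1)
  expect_equal(unname(same$ln_ratio), 0)

  # antisymmetry under swap, on arbitrary values
  set.seed(1)
  a <- matrix(rexp(50, 0.1) + 1, 10, 5)
  b <- matrix(rexp(50, 0.1) + 1, 10, 5)
  expect_equal(paired_fold_change(a, b)$fc,
               1 / paired_fold_change(b, a)$fc, tolerance = 1e-12)
  # ln(FC) = mean per-line LN ratio, exactly
  pf2 <- paired_fold_change(a, b)
  expect_equal(pf2$ln_ratio, rowMeans(log(a / b)), tolerance = 1e-12)

  expect_error(paired_fold_change(matrix(1, 1, 2), matrix(c(1, 0), 1, 2)),
               "pseudocount")
})

test_that("paired t matches the closed-form t distribution", {
  lr <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  tstat <- mean(lr) / (sd(lr) / sqrt(5))
  expect_equal(paired_t(lr), 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)

  expect_equal(paired_t(c(1, -1)), 1)          # t = 0
  expect_true(is.na(paired_t(rep(0, 5))))      # zero variance: flagged
  expect_error(paired_t(0.3), "two lines")

  # matrix form agrees with t.test row by row
  set.seed(2)
  m <- matrix(rnorm(40, 0.1, 0.3), 8, 5)
  expect_equal(unname(paired_t(m)),
               apply(m, 1, function(r) stats::t.test(r)$p.value),
               tolerance = 1e-12)
})

test_that("BH q-values follow the step-up definition", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), c(0.005, 0.025, 1 / 30, 0.0375, 0.04),
               tolerance = 1e-12)
  expect_equal(bh_fdr(0.042), 0.042)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  # NA p-values are excluded from the ranking (m = number of valid tests)
  expect_equal(bh_fdr(c(p, NA)), c(0.005, 0.025, 1 / 30, 0.0375, 0.04, NA),
               tolerance = 1e-12)
  # q >= p and monotone in p
  set.seed(3)
  pr <- runif(100)
  q <- bh_fdr(pr)
  expect_true(all(q >= pr - 1e-12))
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calls apply the joint FC and p rule with inclusive bounds", {
  rec <- data.frame(fc = c(2.5, 2.5, 0.5, 2, 1), ln_ratio = NA,
                    p_paired = c(5e-4, 2e-3, 1e-5, 9.99e-4, 1e-6))
  out <- call_degs(rec)
  expect_equal(as.character(out$call), c("up", "none", "down", "up", "none"))
  expect_identical(attr(out, "n_up"), 2L)
  expect_identical(attr(out, "n_down"), 1L)
})

test_that("expression filter applies inclusive thresholds per scope", {
  m <- matrix(c(rep(0, 9), 10,
                rep(0, 10),
                5, 15, rep(10, 8)), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("S", 1:10)))
  expect_identical(expression_filter(m, scope = "any_sample"), c("a", "c"))
  expect_identical(expression_filter(m, scope = "mean"), "c")
  expect_identical(expression_filter(m[, 1:2], scope = "mean",
                                     threshold = 10), "c")  # mean (5,15)=10
})

test_that("cross-species ratios reproduce the reference-table classification", {
  # two genes constructed to land on opposite sides of the comparison table:
  # one ~15x higher in deermouse, one ~300x higher in mouse
  set.seed(4)
  mk <- function(means) {
    m <- t(vapply(means, function(mu) mu * exp(rnorm(5, 0, 0.15)),
                  numeric(5)))
    rownames(m) <- names(means)
    m
  }
  P <- mk(c(Arg1 = 14.6, Ass1 = 0.03, Gapdh = 1))
  M <- mk(c(Arg1 = 1.0, Ass1 = 10, Gapdh = 1))
  out <- cross_species_ratio(P, M)
  arg1 <- out[out$gene == "Arg1", ]
  ass1 <- out[out$gene == "Ass1", ]
  expect_gt(arg1$ratio_PM, 10)            # higher-in-P side of the table
  expect_lt(arg1$p_between, 0.01)
  expect_gt(1 / ass1$ratio_PM, 100)       # higher-in-M side
  expect_lt(ass1$p_between, 0.01)

  ident <- matrix(5, 2, 5, dimnames = list(c("g1", "g2"), NULL))
  expect_equal(cross_species_ratio(ident, ident)$ratio_PM, c(1, 1))

  expect_message(
    cross_species_ratio(matrix(1, 1, 2, dimnames = list("g1", NULL)) + 1,
                        matrix(1, 2, 2,
                               dimnames = list(c("g1", "gX"), NULL)) + 1),
    "gX")
})

test_that("species specificity needs a tenfold fold-change difference", {
  expect_identical(
    as.character(classify_specificity(c(25, 8, 1), c(2, 4, 10))),
    c("P_specific", "shared", "M_specific"))  # 12.5x; 2x; boundary 10x
  expect_error(classify_specificity(0, 1), "positive")
  expect_error(classify_specificity(Inf, 1), "finite")
})

test_that("isoform concordance flags exactly the perturbed gene", {
  set.seed(5)
  genes <- paste0("g", 1:50)
  base <- data.frame(feature_id = genes,
                     fc = exp(rnorm(50, 0, 0.1)),
                     q_bh = runif(50, 0.2, 1))
  base$fc[7] <- 4; base$q_bh[7] <- 0.001   # a clear DEG in both sets
  expect_identical(nrow(isoform_concordance(base, base)), 0L)

  other <- base
  other$fc[13] <- 5; other$q_bh[13] <- 0.002  # DEG only under reference 2
  out <- isoform_concordance(base, other)
  expect_identical(out$gene, "g13")
  expect_identical(out$call_set1, "none")
  expect_identical(out$call_set2, "up")

  expect_error(isoform_concordance(base, base[-1, ]), "g1")
})

test_that("Fisher exact p equals the full-enumeration oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 7, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                 tolerance = 1e-8)
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Kruskal-Wallis ranks behave at the extremes", {
  # (1,2,3) vs (4,5,6): H is maximal over all 3/3 splits of ranks 1..6
  h_obs <- attr(kruskal_wallis(list(1:3, 4:6)), "statistic")
  splits <- combn(6, 3)
  h_all <- apply(splits, 2, function(idx) {
    g <- factor(seq_len(6) %in% idx)
    unname(stats::kruskal.test(1:6, g)$statistic)
  })
  expect_equal(h_obs, max(h_all), tolerance = 1e-12)

  dup <- kruskal_wallis(list(c(2, 9, 4), c(2, 9, 4)))
  expect_equal(attr(dup, "statistic"), 0, tolerance = 1e-12)
  expect_true(is.na(kruskal_wallis(list(c(1, 1), c(1, 1)))))

  # permuted labels of one sample give approximately uniform p (small n,
  # permutation oracle): the p-value at alpha = 0.5 rejects ~half the time
  set.seed(7)
  x <- rnorm(8)
  ps <- replicate(200, {
    perm <- sample(x)
    kruskal_wallis(list(perm[1:4], perm[5:8]))
  })
  expect_equal(mean(ps < 0.5), 0.5, tolerance = 0.15)
})
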