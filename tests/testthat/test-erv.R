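test_that("length filter is inclusive at the boundary and idempotent", {
  rec <- data.frame(erv_id = c("a", "b", "c"),
                    length_bp = c(300, 500, 9543))
  out <- filter_min_length(rec)
  expect_identical(out$kept$erv_id, c("b", "c"))
  expect_equal(out$excluded_fraction, 1 / 3)
  again <- filter_min_length(out$kept)
  expect_identical(again$kept, out$kept)
  expect_equal(again$excluded_fraction, 0)

  empty <- filter_min_length(rec[0, ])
  expect_identical(nrow(empty$kept), 0L)
  expect_true(is.na(empty$excluded_fraction))
})

test_that("Z-scores use the reference set's sample (n-1) sd", {
  ref <- c(0, 2)
  expect_equal(zscore_lengths(1, ref), 0)            # x = mean
  expect_equal(zscore_lengths(2, ref), 1 / sqrt(2))  # sd = sqrt(2)
  set.seed(1)
  r <- rlnorm(500, 6, 1)
  z <- zscore_lengths(r, r)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore_tpm(1, c(3, 3, 3)), "zero")
  # the TPM variant is the same standardization on the expressed subset
  expect_equal(zscore_tpm(12, r), zscore_lengths(12, r))
})

test_that("skewness is the adjusted Fisher-Pearson coefficient", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_gt(skewness(c(0, 0, 1)), 0)
  expect_true(is.na(skewness(c(2, 2, 2))))
  set.seed(2)
  x <- rlnorm(200, 0, 0.9)
  # direct-moment oracle
  n <- length(x)
  direct <- n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / sd(x))^3)
  expect_equal(skewness(x), direct, tolerance = 1e-12)
  # independent cross-check against e1071's adjusted (type 2) convention
  expect_equal(skewness(x), e1071::skewness(x, type = 2), tolerance = 1e-9)
})

test_that("length summaries nest the median inside the IQR", {
  set.seed(3)
  len <- round(rlnorm(400, 6.5, 0.8))
  s <- length_distribution_summary(len)
  expect_identical(s$n, 400L)
  expect_equal(sum(s$size_class_counts), 400)
  expect_true(s$iqr[1] <= s$median_bp && s$median_bp <= s$iqr[2])
})

test_that("top-k by TPM is deterministic under the documented tie rule", {
  rec <- data.frame(erv_id = c("e1", "e2", "e3", "e4"),
                    mean_tpm = c(5, 9, 5, 1),
                    length_bp = c(700, 100, 900, 50))
  expect_identical(top_k_by_tpm(rec, 4)$top$erv_id,
                   c("e2", "e3", "e1", "e4"))
  expect_identical(top_k_by_tpm(rec, 1)$top$erv_id, "e2")
  # tie at the k-th rank: longer length wins, then id, every run
  expect_identical(top_k_by_tpm(rec, 2)$top$erv_id, c("e2", "e3"))
  expect_error(top_k_by_tpm(rec, 5), "exceeds")
})

test_that("upregulated-repeat subset applies inclusive FC, exclusive p", {
  deg <- data.frame(erv_id = c("a", "b", "c"),
                    fc = c(2, 1.99, 3), p_paired = c(9e-4, 1e-6, 1e-3))
  out <- erv_deg_subset(deg)
  expect_identical(out$erv_id, "a")
  expect_identical(attr(out, "n"), 1L)
})

test_that("passage contrast reports the printed percentage convention", {
  expect_equal(percent(21, 87, 0), 24)
  expect_equal(percent(19, 21, 0), 90)
  expect_equal(percent(832, 10843, 1), 7.7)
  expect_equal(percent(1136, 10843, 1), 10.5)
  expect_equal(percent(10843, 103397, 1), 10.5)
  expect_equal(percent(1, 8, 1), 12.5)  # exact half rounds up, never to even
  expect_error(percent(1, 0), "positive")

  set.seed(4)
  n <- 300
  tpm_mat <- matrix(rnbinom(n * 6, mu = 60, size = 20) + 0.0, n, 6,
                    dimnames = list(sprintf("e%03d", 1:n), paste0("S", 1:6)))
  up_idx <- 1:20; down_idx <- 21:35
  tpm_mat[up_idx, 1:3] <- tpm_mat[up_idx, 1:3] * 8
  tpm_mat[down_idx, 4:6] <- tpm_mat[down_idx, 4:6] * 8
  groups <- rep(c("P4", "P47"), each = 3)
  out <- passage_contrast(tpm_mat, groups, fc_min = 4, tpm_min = 10,
                          q_max = 0.05)
  expect_gt(mean(rownames(tpm_mat)[up_idx] %in% out$up), 0.8)
  expect_gt(mean(rownames(tpm_mat)[down_idx] %in% out$down), 0.8)
  # features equal in both groups are never called
  expect_false(any(setdiff(rownames(tpm_mat),
                           rownames(tpm_mat)[c(up_idx, down_idx)]) %in%
                   c(out$up, out$down)))
  expect_equal(out$pct_up,
               percent(out$n_up, out$n_universe, 1))
  # sign convention: higher in the second group means negative log2 FC
  expect_true(all(out$table$log2_fc[match(out$down,
                                          out$table$feature_id)] < 0))
  expect_error(passage_contrast(tpm_mat, rep("P4", 6)), "two groups")
})

test_that("OLS bands keep the pointwise ordering and nail noiseless fits", {
  x <- c(1, 2, 3, 4)
  fit0 <- ols_with_bands(x, 3 + 2 * x)
  expect_equal(fit0$slope, 2, tolerance = 1e-10)
  expect_equal(fit0$intercept, 3, tolerance = 1e-10)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit0$bands$lcl, fit0$bands$ucl, tolerance = 1e-8)

  set.seed(5)
  xr <- runif(40, 0, 100)
  fit <- ols_with_bands(xr, 5 + 0.3 * xr + rnorm(40, 0, 4))
  b <- fit$bands
  expect_true(all(b$lpl <= b$lcl & b$lcl <= b$mean &
                  b$mean <= b$ucl & b$ucl <= b$upl))
  # prediction band strictly contains the confidence band
  expect_true(all(b$lpl < b$lcl & b$upl > b$ucl))
  nb <- predict(fit, c(-10, 0, 50, 200))
  expect_true(all(nb$lpl < nb$lcl & nb$ucl < nb$upl))
  expect_error(ols_with_bands(rep(1, 5), rnorm(5)), "constant")
})
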