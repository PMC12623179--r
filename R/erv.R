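# ERV/TE expression and length analyses: the >=500 bp length filter,
# Z-scores against the complete reference set, adjusted Fisher-Pearson
# skewness, top-k expression subsets, DEG subsets at the study thresholds,
# passage contrasts, and OLS regression of expression on length with 95%
# confidence (LCL/UCL) and prediction (LPL/UPL) bands.

#' Filter ERV/TE records on a minimum length
#'
#' Keeps records with `length_bp >= min_bp` (boundary inclusive) and reports
#' the excluded fraction. Idempotent.
#'
#' @param records Data frame with a `length_bp` column.
#' @param min_bp Minimum length in bp (default 500).
#' @return List with `kept` (data frame) and `excluded_fraction` (`NA` for
#'   empty input).
#' @export
filter_min_length <- function(records, min_bp = 500) {
  stopifnot("length_bp" %in% names(records))
  if (nrow(records) == 0)
    return(list(kept = records, excluded_fraction = NA_real_))
  keep <- records$length_bp >= min_bp
  list(kept = records[keep, , drop = FALSE],
       excluded_fraction = mean(!keep))
}

# Shared Z-score core: sample (n-1) standard deviation of the reference.
zscore_against <- function(query, reference) {
  stopifnot(length(reference) >= 2)
  s <- stats::sd(reference)
  if (s == 0) stop("reference standard deviation is zero")
  (query - mean(reference)) / s
}

#' Z-scores of lengths against a complete reference set
#'
#' Standardizes query lengths by the mean and sample (n-1) standard
#' deviation of the complete reference set's length distribution.
#'
#' @param query Numeric vector of query lengths (bp).
#' @param reference Lengths of the complete reference set.
#' @return Numeric vector of Z-scores.
#' @export
zscore_lengths <- function(query, reference) zscore_against(query, reference)

#' Z-scores of mean TPM against the expressed reference subset
#'
#' As [zscore_lengths()], with the reference population being the
#' TPM-filtered (expressed) subset of the reference set.
#'
#' @param query Mean TPM values to standardize.
#' @param reference Mean TPM of the expressed reference subset.
#' @return Numeric vector of Z-scores.
#' @export
zscore_tpm <- function(query, reference) zscore_against(query, reference)

#' Adjusted Fisher-Pearson skewness coefficient
#'
#' The standardized third moment with the small-sample adjustment
#' `n / ((n-1)(n-2))` and the sample (n-1) standard deviation — the common
#' spreadsheet and statistics-package convention.
#'
#' @param values Numeric vector, n >= 3.
#' @return Skewness, or `NA` for constant input (undefined flag).
#' @export
skewness <- function(values) {
  n <- length(values)
  stopifnot(n >= 3)
  s <- stats::sd(values)
  if (s == 0) return(NA_real_)
  n / ((n - 1) * (n - 2)) * sum(((values - mean(values)) / s)^3)
}

#' Summarize a length distribution
#'
#' @param lengths_bp Numeric vector of lengths.
#' @param bin_bp Width of histogram size classes (default 500 bp).
#' @param max_bp Upper edge of the last bin (default 9600 bp; longer
#'   lengths fall in an overflow bin).
#' @return List: n, mean_bp, median_bp, iqr (named length-2 vector),
#'   skewness, size_class_counts.
#' @export
length_distribution_summary <- function(lengths_bp, bin_bp = 500,
                                        max_bp = 9600) {
  stopifnot(length(lengths_bp) >= 1)
  breaks <- c(seq(0, max_bp, by = bin_bp), Inf)
  counts <- table(cut(lengths_bp, breaks, right = FALSE))
  list(n = length(lengths_bp),
       mean_bp = mean(lengths_bp),
       median_bp = stats::median(lengths_bp),
       iqr = stats::quantile(lengths_bp, c(0.25, 0.75), names = FALSE),
       skewness = if (length(lengths_bp) >= 3) skewness(lengths_bp)
                  else NA_real_,
       size_class_counts = counts)
}

#' Top-k records by mean TPM
#'
#' Returns the `k` records of highest mean TPM with a length-distribution
#' summary attached. Ties at the k-th rank are broken deterministically by
#' longer length, then by id.
#'
#' @param records Data frame with columns `erv_id`, `mean_tpm` and
#'   `length_bp`.
#' @param k Number of records to keep (`k <= nrow(records)`).
#' @return List with `top` (data frame) and `length_summary`.
#' @export
top_k_by_tpm <- function(records, k) {
  stopifnot(all(c("erv_id", "mean_tpm", "length_bp") %in% names(records)))
  if (k > nrow(records))
    stop("k = ", k, " exceeds the ", nrow(records), " available records")
  ord <- order(-records$mean_tpm, -records$length_bp, records$erv_id)
  top <- records[ord[seq_len(k)], , drop = FALSE]
  rownames(top) <- NULL
  list(top = top,
       length_summary = length_distribution_summary(top$length_bp))
}

#' ERV/TE DEG subset at joint fold-change and p thresholds
#'
#' Keeps records with `fc >= fc_min` (boundary inclusive) and paired-t
#' `p < p_max` — the upregulated-repeat criterion of the agonist contrast.
#'
#' @param deg Data frame with columns `fc` and `p_paired`.
#' @param fc_min Minimum fold change (default 2).
#' @param p_max Paired-t p threshold (default 0.001).
#' @return The qualifying subset, with attribute `n` (its size).
#' @export
erv_deg_subset <- function(deg, fc_min = 2, p_max = 0.001) {
  stopifnot(all(c("fc", "p_paired") %in% names(deg)))
  keep <- !is.na(deg$p_paired) & deg$fc >= fc_min & deg$p_paired < p_max
  out <- deg[keep, , drop = FALSE]
  structure(out, n = nrow(out))
}

#' Low- versus high-passage expression contrast
#'
#' Compares group-mean TPM between two passage groups over the expressed
#' universe (mean TPM across all samples >= `tpm_min`). The fold change is
#' reported as log2 of the group-1 to group-2 mean ratio, so negative
#' values denote higher expression in the second group. P-values are Welch
#' t-tests on log2(TPM + pseudocount) with BH adjustment unless an FDR
#' column is supplied.
#'
#' @param tpm_mat Matrix of TPM values (features x samples).
#' @param groups Factor/character of length `ncol(tpm_mat)` with exactly two
#'   levels; the first level is the reference (e.g. low passage).
#' @param fc_min Minimum absolute fold change (default 4).
#' @param tpm_min Expressed-universe threshold on mean TPM (default 10).
#' @param q_max FDR threshold (default 0.01).
#' @param pseudocount Added before ratios and logs (default 0.5).
#' @param fdr Optional externally supplied FDR p-values (named by feature or
#'   ordered as `rownames(tpm_mat)`), e.g. from a negative-binomial GLM fit;
#'   thresholds are then applied to those instead.
#' @return List: `table` (feature_id, mean_tpm, log2_fc, q), `up`/`down`
#'   feature ids, counts `n_up`/`n_down`, universe size `n_universe`, and
#'   one-decimal percentages `pct_up`/`pct_down`.
#' @export
passage_contrast <- function(tpm_mat, groups, fc_min = 4, tpm_min = 10,
                             q_max = 0.01, pseudocount = 0.5, fdr = NULL) {
  tpm_mat <- unclass(tpm_mat)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || length(groups) != ncol(tpm_mat))
    stop("`groups` must assign every sample to one of exactly two groups")
  if (any(table(groups) == 0)) stop("empty group")
  g1 <- groups == levels(groups)[1]
  universe <- rowMeans(tpm_mat) >= tpm_min
  m <- tpm_mat[universe, , drop = FALSE]
  mean1 <- rowMeans(m[, g1, drop = FALSE])
  mean2 <- rowMeans(m[, !g1, drop = FALSE])
  log2_fc <- log2((mean1 + pseudocount) / (mean2 + pseudocount))
  if (is.null(fdr)) {
    lx <- log2(m + pseudocount)
    q <- bh_fdr(welch_t_rows(lx[, g1, drop = FALSE],
                             lx[, !g1, drop = FALSE]))
  } else {
    q <- if (!is.null(names(fdr))) fdr[rownames(m)] else fdr[universe]
  }
  sig <- !is.na(q) & q < q_max & abs(log2_fc) >= log2(fc_min)
  up <- rownames(m)[sig & log2_fc > 0]
  down <- rownames(m)[sig & log2_fc < 0]
  n_universe <- nrow(m)
  list(table = data.frame(feature_id = rownames(m),
                          mean_tpm = rowMeans(m), log2_fc = log2_fc,
                          q = unname(q), row.names = NULL),
       up = up, down = down, n_up = length(up), n_down = length(down),
       n_universe = n_universe,
       pct_up = percent(length(up), n_universe, 1),
       pct_down = percent(length(down), n_universe, 1))
}

# Row-wise Welch two-sample t-test p-values.
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  va <- rowSums((a - rowMeans(a))^2) / (na - 1)
  vb <- rowSums((b - rowMeans(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (rowMeans(a) - rowMeans(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- NA_real_
  p
}

#' OLS regression with confidence and prediction bands
#'
#' Ordinary least squares of `y` on `x` with t-based pointwise bands at the
#' stated level: LCL/UCL for the conditional mean and LPL/UPL for a new
#' observation, satisfying LPL <= LCL <= mean <= UCL <= UPL at every x.
#'
#' @param x,y Numeric vectors (n >= 3; x not constant).
#' @param level Band level (default 0.95).
#' @return Object of class `ols_bands`: slope, intercept, r_squared,
#'   slope_ci, and per-point `bands` (x, mean, lcl, ucl, lpl, upl); the
#'   underlying `lm` fit is kept in `$model`.
#' @export
ols_with_bands <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  ci <- stats::predict(fit, interval = "confidence", level = level)
  # in-sample prediction bands are wanted here; silence predict.lm's note
  pi <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    slope_ci = unname(suppressWarnings(
      stats::confint(fit, "x", level = level))[1, ]),
    bands = data.frame(x = x, mean = ci[, "fit"],
                       lcl = ci[, "lwr"], ucl = ci[, "upr"],
                       lpl = pi[, "lwr"], upl = pi[, "upr"]),
    level = level, model = fit), class = "ols_bands")
}

#' Evaluate fitted mean and bands at new predictor values
#'
#' @param object An `ols_bands` fit.
#' @param newx Numeric vector of predictor values.
#' @param ... Unused.
#' @return Data frame: x, mean, lcl, ucl, lpl, upl.
#' @export
predict.ols_bands <- function(object, newx, ...) {
  nd <- data.frame(x = newx)
  ci <- stats::predict(object$model, nd, interval = "confidence",
                       level = object$level)
  pi <- suppressWarnings(
    stats::predict(object$model, nd, interval = "prediction",
                   level = object$level))
  data.frame(x = newx, mean = ci[, "fit"], lcl = ci[, "lwr"],
             ucl = ci[, "upr"], lpl = pi[, "lwr"], upl = pi[, "upr"])
}

#' @export
print.ols_bands <- function(x, ...) {
  cat(sprintf("<ols_bands> y = %.4g + %.4g x, R^2 = %.4f, %g%% bands\n",
              x$intercept, x$slope, x$r_squared, 100 * x$level))
  invisible(x)
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up (never banker's
#' rounding) to the stated number of decimals — the convention that
#' reproduces every printed count/percentage pair in the study's tables.
#'
#' @param numerator,denominator Non-negative counts; denominator > 0.
#' @param decimals Decimal places (default 0).
#' @return The rounded percentage.
#' @export
percent <- function(numerator, denominator, decimals = 0) {
  stopifnot(numerator >= 0)
  if (denominator <= 0) stop("denominator must be positive")
  f <- 10^decimals
  floor(100 * numerator / denominator * f + 0.5) / f
}
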