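# Small self-contained calculators: population doubling time from a
# log-linear growth fit, and proteomic peptide coverage of a protein.

#' Doubling time from a log-linear growth regression
#'
#' Ordinary least squares of log10 cell density on time (days); the
#' doubling time is `24 * log10(2) / slope` hours. A non-positive slope
#' (no growth) gives an `NA` doubling time, flagged rather than fatal.
#' The estimate is invariant to rescaling of the density unit.
#'
#' @param time_days Non-negative times in days, strictly increasing.
#' @param density_cells_per_ml Positive cell densities at those times.
#' @return List: doubling_time_h, slope_log10_per_day, r_squared.
#' @export
doubling_time <- function(time_days, density_cells_per_ml) {
  stopifnot(length(time_days) == length(density_cells_per_ml),
            length(time_days) >= 2)
  if (any(diff(time_days) <= 0))
    stop("times must be strictly increasing")
  if (any(density_cells_per_ml <= 0))
    stop("densities must be positive")
  fit <- stats::lm(log10(density_cells_per_ml) ~ time_days)
  slope <- unname(stats::coef(fit)[2])
  # noiseless exponential series are legitimate input: a perfect fit is fine
  r2 <- if (length(time_days) > 2)
    suppressWarnings(summary(fit)$r.squared) else 1
  list(doubling_time_h = if (slope > 0) 24 * log10(2) / slope else NA_real_,
       slope_log10_per_day = slope, r_squared = r2)
}

#' Peptide coverage of a protein sequence
#'
#' Maps each peptide to every exact-substring occurrence in the protein and
#' reports the fraction of protein positions covered by the union of
#' matches (overlaps are not double-counted). Unmatched peptides are
#' reported, not fatal. Order-independent and idempotent under peptide
#' duplication.
#'
#' @param protein Amino-acid string (non-empty).
#' @param peptides Character vector of peptide sequences.
#' @return List: coverage (fraction in \[0,1\]), covered (logical mask of
#'   protein positions), n_covered, unmatched (peptides with no occurrence).
#' @export
peptide_coverage <- function(protein, peptides) {
  stopifnot(is.character(protein), length(protein) == 1, nchar(protein) > 0)
  n <- nchar(protein)
  covered <- logical(n)
  unmatched <- character(0)
  for (pep in peptides) {
    if (nchar(pep) == 0) next
    # zero-width lookahead finds overlapping occurrences too
    hits <- gregexpr(paste0("(?=", gsub("([^A-Za-z0-9])", "\\\\\\1", pep),
                            ")"), protein, perl = TRUE)[[1]]
    if (hits[1] == -1) {
      unmatched <- c(unmatched, pep)
      next
    }
    for (h in hits) covered[h:(h + nchar(pep) - 1)] <- TRUE
  }
  list(coverage = mean(covered), covered = covered,
       n_covered = sum(covered), unmatched = unique(unmatched))
}
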