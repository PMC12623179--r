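# Paired fold-change / t-test differential expression at the study's
# thresholds, cross-species Gapdh-ratio comparison, species-specificity
# classification, and isoform-reference concordance. Fold change is the
# geometric mean of per-line treated/control ratios, so ln(FC) equals the
# mean of per-line LN ratios exactly.

#' Paired fold change and LN ratio per feature
#'
#' Ratios are formed within a cell line as `(treated + pc)/(control + pc)`;
#' the fold change is the geometric mean of the per-line ratios and
#' `ln_ratio` its natural logarithm (= mean per-line LN ratio).
#'
#' @param treated,control Numeric matrices (features x cell lines) aligned
#'   on both dimensions; vectors are treated as single-feature matrices.
#' @param pseudocount Non-negative value added to both sides before the
#'   ratio. With pseudocount 0 any zero in `control` is an error.
#' @return List with `fc`, `ln_ratio` (named per feature) and `ln_ratios`
#'   (features x lines matrix of per-line LN ratios).
#' @export
paired_fold_change <- function(treated, control, pseudocount = 0) {
  if (is.null(dim(treated))) treated <- t(as.matrix(treated))
  if (is.null(dim(control))) control <- t(as.matrix(control))
  stopifnot(identical(dim(treated), dim(control)), pseudocount >= 0)
  if (!is.null(colnames(treated)) && !is.null(colnames(control)) &&
      !identical(colnames(treated), colnames(control)))
    stop("treated and control must be indexed by the same cell lines")
  if (pseudocount == 0 && any(control == 0))
    stop("zero in control with pseudocount 0; supply a positive pseudocount")
  lr <- log((treated + pseudocount) / (control + pseudocount))
  ln_ratio <- rowMeans(lr)
  list(fc = exp(ln_ratio), ln_ratio = ln_ratio, ln_ratios = lr)
}

#' Two-tailed paired t-test of LN ratios against zero
#'
#' One-sample t-test of the per-line LN ratios' mean against 0. Zero
#' variance (all ratios identical) gives `NA` — an explicit undefined flag,
#' never an artificial 0 — and such features are excluded from FDR ranking.
#'
#' @param ln_ratios Numeric vector (one feature) or matrix
#'   (features x lines).
#' @return P-value, or vector of p-values for a matrix input.
#' @export
paired_t <- function(ln_ratios) {
  if (is.null(dim(ln_ratios))) ln_ratios <- t(as.matrix(ln_ratios))
  n <- ncol(ln_ratios)
  if (n < 2) stop("paired t-test needs at least two lines")
  m <- rowMeans(ln_ratios)
  v <- rowSums((ln_ratios - m)^2) / (n - 1)
  p <- rep(NA_real_, nrow(ln_ratios))
  ok <- v > 0 & rowSums(!is.finite(ln_ratios)) == 0
  tstat <- m[ok] / sqrt(v[ok] / n)
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 1)
  names(p) <- rownames(ln_ratios)
  if (length(p) == 1) unname(p) else p
}

#' Benjamini-Hochberg step-up q-values
#'
#' Computed over the defined p-values only (`NA` entries are excluded from
#' the ranking and returned as `NA`), with `m` = number of valid tests.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Vector of q-values, same length and names.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  names(q) <- names(pvalues)
  q
}

#' Call differentially expressed features at joint FC and p thresholds
#'
#' A feature is called `up` iff `fc >= fc_up` and `p < p_max`, `down` iff
#' `fc <= fc_down` and `p < p_max`, otherwise `none` (undefined p never
#' yields a call).
#'
#' @param records Data frame with columns `fc` and `p_paired` (and
#'   optionally more, passed through).
#' @param fc_up,fc_down,p_max Calling thresholds (defaults 2, 0.5, 0.001).
#' @return The data frame with a `call` column, plus attributes `n_up` and
#'   `n_down`.
#' @export
call_degs <- function(records, fc_up = 2, fc_down = 0.5, p_max = 0.001) {
  stopifnot(all(c("fc", "p_paired") %in% names(records)))
  p <- records$p_paired
  sig <- !is.na(p) & p < p_max
  call <- rep("none", nrow(records))
  call[sig & records$fc >= fc_up] <- "up"
  call[sig & records$fc <= fc_down] <- "down"
  records$call <- factor(call, levels = c("up", "down", "none"))
  structure(records, n_up = sum(call == "up"), n_down = sum(call == "down"))
}

#' Paired differential expression table
#'
#' Assembles per-feature fold change, LN ratio, paired-t p, BH q and call
#' from aligned treated/control matrices.
#'
#' @inheritParams paired_fold_change
#' @inheritParams call_degs
#' @param pseudocount Pseudocount applied at ratio time (default 0.5 on the
#'   count/normalized scale; a message is emitted when it is actually used).
#' @return Data frame: feature_id, fc, ln_ratio, p_paired, q_bh, call; with
#'   `n_up`/`n_down` attributes.
#' @export
paired_deg <- function(treated, control, pseudocount = 0.5,
                       fc_up = 2, fc_down = 0.5, p_max = 0.001) {
  if (pseudocount > 0 && (any(treated == 0) || any(control == 0)))
    message("pseudocount ", pseudocount, " applied to zero values")
  pf <- paired_fold_change(treated, control, pseudocount)
  p <- paired_t(pf$ln_ratios)
  records <- data.frame(
    feature_id = if (!is.null(rownames(pf$ln_ratios)))
      rownames(pf$ln_ratios) else seq_along(pf$fc),
    fc = unname(pf$fc), ln_ratio = unname(pf$ln_ratio),
    p_paired = unname(p), q_bh = unname(bh_fdr(p)))
  call_degs(records, fc_up, fc_down, p_max)
}

#' Split a matrix into treated and control blocks paired by cell line
#'
#' @param values Matrix (features x samples) whose columns are described by
#'   `meta`.
#' @param meta Sample metadata (see [count_matrix()]).
#' @param species Species to select.
#' @param dose Treated dose in ug/mL (default 1).
#' @return List with matrices `treated` and `control`, columns ordered by
#'   cell line and named by it.
#' @export
paired_design_matrices <- function(values, meta, species, dose = 1) {
  values <- unclass(values)
  tr <- meta$species == species & meta$dose_ug_per_ml == dose
  ct <- meta$species == species & meta$dose_ug_per_ml == 0
  if (!any(tr) || !any(ct))
    stop("no samples for species '", species, "' at the requested doses")
  lines <- sort(unique(meta$cell_line[tr]))
  if (!setequal(lines, unique(meta$cell_line[ct])))
    stop("each cell line needs both a control and a treated sample")
  pick <- function(sel) {
    idx <- vapply(lines, function(l) which(sel & meta$cell_line == l)[1],
                  integer(1))
    m <- values[, idx, drop = FALSE]
    colnames(m) <- lines
    m
  }
  list(treated = pick(tr), control = pick(ct))
}

#' Filter features on a TPM expression threshold
#'
#' @param tpm_mat A `normalized_matrix` of TPM values (or plain matrix).
#' @param threshold Minimum TPM (default 10, inclusive).
#' @param scope `"any_sample"` keeps a feature whose maximum TPM reaches the
#'   threshold in at least one sample; `"mean"` applies it to the mean over
#'   all samples.
#' @return Character vector of retained feature ids.
#' @export
expression_filter <- function(tpm_mat, threshold = 10,
                              scope = c("any_sample", "mean")) {
  scope <- match.arg(scope)
  values <- unclass(tpm_mat)
  stat <- if (scope == "any_sample") apply(values, 1, max)
          else rowMeans(values)
  rownames(values)[stat >= threshold]
}

#' Cross-species expression ratio on the Gapdh-ratio scale
#'
#' For each gene shared between the two species' matrices, the ratio of
#' species means of Gapdh-normalized values, with an unpaired two-tailed
#' t-test on the LN values. Genes absent from one species are excluded and
#' reported via a message.
#'
#' @param norm_P,norm_M Gapdh-ratio `normalized_matrix` objects (one
#'   condition each), rownames = gene symbols.
#' @param pseudocount Added before LN for the t-test and means when zeros
#'   occur (default 0; zeros with pseudocount 0 are an error).
#' @return Data frame: gene, ratio_PM, p_between.
#' @export
cross_species_ratio <- function(norm_P, norm_M, pseudocount = 0) {
  shared <- intersect(rownames(norm_P), rownames(norm_M))
  dropped <- setdiff(union(rownames(norm_P), rownames(norm_M)), shared)
  if (length(dropped))
    message(length(dropped), " gene(s) absent in one species excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  P <- unclass(norm_P)[shared, , drop = FALSE] + pseudocount
  M <- unclass(norm_M)[shared, , drop = FALSE] + pseudocount
  if (any(P <= 0) || any(M <= 0))
    stop("non-positive values; supply a positive pseudocount")
  ratio <- rowMeans(P) / rowMeans(M)
  lp <- log(P); lm_ <- log(M)
  nP <- ncol(P); nM <- ncol(M)
  vP <- apply(lp, 1, stats::var); vM <- apply(lm_, 1, stats::var)
  se <- sqrt(vP / nP + vM / nM)
  tt <- (rowMeans(lp) - rowMeans(lm_)) / se
  df <- (vP / nP + vM / nM)^2 /
    ((vP / nP)^2 / (nP - 1) + (vM / nM)^2 / (nM - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se == 0] <- NA_real_
  data.frame(gene = shared, ratio_PM = unname(ratio), p_between = unname(p))
}

#' Classify species specificity of treatment responses
#'
#' A response is specific to one species when its fold change is at least
#' ten times the other species' fold change (boundary inclusive).
#'
#' @param fc_P,fc_M Positive finite fold changes (vectors recycled to common
#'   length).
#' @param fold Specificity ratio threshold (default 10).
#' @return Factor with levels `P_specific`, `M_specific`, `shared`.
#' @export
classify_specificity <- function(fc_P, fc_M, fold = 10) {
  if (any(!is.finite(fc_P)) || any(!is.finite(fc_M)) ||
      any(fc_P <= 0) || any(fc_M <= 0))
    stop("fold changes must be finite and positive")
  out <- ifelse(fc_P / fc_M >= fold, "P_specific",
                ifelse(fc_M / fc_P >= fold, "M_specific", "shared"))
  factor(out, levels = c("P_specific", "M_specific", "shared"))
}

#' Genes whose DEG call differs between two isoform reference sets
#'
#' Compares calls at an FDR threshold between DEG tables produced with two
#' alternative isoform references over the same gene universe.
#'
#' @param deg_set_1,deg_set_2 Data frames with columns `feature_id`, `fc`
#'   and `q_bh` (e.g. from [paired_deg()]), keyed by gene.
#' @param q_max FDR threshold for a call (default 0.05).
#' @param fc_up,fc_down Direction thresholds (defaults 2 and 0.5).
#' @return Data frame of discordant genes with the call under each
#'   reference; zero rows when the sets agree.
#' @export
isoform_concordance <- function(deg_set_1, deg_set_2, q_max = 0.05,
                                fc_up = 2, fc_down = 0.5) {
  u1 <- deg_set_1$feature_id; u2 <- deg_set_2$feature_id
  if (!setequal(u1, u2))
    stop("gene universes differ; symmetric difference: ",
         paste(c(setdiff(u1, u2), setdiff(u2, u1)), collapse = ", "))
  call_at <- function(d) {
    sig <- !is.na(d$q_bh) & d$q_bh < q_max
    ifelse(sig & d$fc >= fc_up, "up",
           ifelse(sig & d$fc <= fc_down, "down", "none"))
  }
  d2 <- deg_set_2[match(u1, u2), , drop = FALSE]
  c1 <- call_at(deg_set_1); c2 <- call_at(d2)
  differ <- c1 != c2
  data.frame(gene = u1[differ], call_set1 = c1[differ],
             call_set2 = c2[differ])
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Sum of hypergeometric probabilities of tables at most as probable as the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return Two-tailed p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != floor(table)))
    stop("table entries must be non-negative integers")
  stats::fisher.test(table)$p.value
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Chi-square approximation with k - 1 degrees of freedom; two groups are
#' allowed (equivalent to a tie-corrected rank-sum test). All values
#' identical gives `NA` (undefined flag).
#'
#' @param groups List of >= 2 numeric vectors (total n >= 3).
#' @return P-value, with the H statistic as attribute `statistic`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1), sum(lengths(groups)) >= 3)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) return(NA_real_)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  structure(kt$p.value, statistic = unname(kt$statistic))
}
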