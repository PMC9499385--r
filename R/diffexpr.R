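#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample scaling factors: per sample, a
#' weighted mean of gene-wise log-ratios against a reference sample after
#' trimming the most extreme 30 percent of M-values and 5 percent of
#' A-values, with inverse-asymptotic-variance weights; factors are
#' normalized to multiply to 1 and the reference sample is the one whose
#' upper-quartile count fraction is closest to the mean. Computed by
#' \code{edgeR::calcNormFactors}, the canonical implementation.
#'
#' @param counts miRNA x sample count matrix (>= 2 samples, nonzero
#'   libraries).
#' @return Named numeric vector of scaling factors (product 1).
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stop("TMM requires at least 2 samples")
  if (any(colSums(counts) == 0))
    stop(sprintf("zero library size for sample(s): %s",
                 paste(colnames(counts)[colSums(counts) == 0], collapse = ", ")))
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  f <- y$samples$norm.factors
  if (any(!is.finite(f)))
    stop("TMM factor not estimable (a sample shares no expressed miRNAs with the reference)")
  stats::setNames(f, colnames(counts))
}

#' TMM-normalized CPM
#'
#' CPM computed on TMM-scaled effective library sizes.
#'
#' @param counts count matrix.
#' @param log return log2 values with a 1-CPM pseudocount.
#' @return Normalized (log2) CPM matrix.
#' @export
tmm_cpm <- function(counts, log = FALSE) {
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  x <- sweep(counts, 2, eff, "/") * 1e6
  if (log) log2(x + 1) else x
}

#' Blocked pairwise differential expression across anticoagulant groups
#'
#' Fits, per miRNA, a negative-binomial generalized linear model with
#' additive subject (blocking) and group effects on TMM-normalized counts,
#' with empirical-Bayes-moderated dispersion, and tests every pairwise
#' group contrast with the quasi-likelihood F-test (edgeR's glmQLFit /
#' glmQLFTest machinery, as is standard for this design). P-values are
#' adjusted by Benjamini-Hochberg pooled across all contrasts as one
#' family.
#'
#' @param counts filtered miRNA x sample count matrix.
#' @param group factor/character of group labels per sample (>= 2 groups).
#' @param subject factor/character of subject IDs per sample; each subject
#'   should appear in >= 2 groups for the blocking term to be useful.
#' @param alpha significance threshold on the adjusted p-value (strict).
#' @param blocked include the subject blocking term (the default); setting
#'   \code{FALSE} drops it, which is only useful for demonstrating why
#'   blocking matters in this paired design.
#' @return A data.frame of class \code{de_results} with one row per miRNA
#'   per contrast: \code{mirna}, \code{contrast} (\code{"B_vs_A"}; log2fc
#'   is B relative to A), \code{log2fc}, \code{mean_log2cpm},
#'   \code{p_value}, \code{adj_p}, \code{significant}.
#' @export
fit_pairwise_de <- function(counts, group, subject, alpha = 0.05,
                            blocked = TRUE) {
  group <- factor(group)
  subject <- factor(subject)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  stopifnot(length(group) == ncol(counts), length(subject) == ncol(counts))

  design <- if (blocked) stats::model.matrix(~ 0 + group + subject)
            else stats::model.matrix(~ 0 + group)
  colnames(design) <- sub("^group", "", colnames(design))
  y <- edgeR::DGEList(counts = counts, group = group)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  ave <- edgeR::aveLogCPM(y)

  pairs <- utils::combn(levels(group), 2, simplify = FALSE)
  out <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    cvec <- numeric(ncol(design))
    names(cvec) <- colnames(design)
    if (!all(c(a, b) %in% colnames(design))) {
      warning(sprintf("contrast %s vs %s not estimable: skipped", b, a))
      next
    }
    cvec[b] <- 1; cvec[a] <- -1
    qlf <- edgeR::glmQLFTest(fit, contrast = cvec)
    tt <- qlf$table
    out[[paste0(b, "_vs_", a)]] <- data.frame(
      mirna = rownames(tt),
      contrast = paste0(b, "_vs_", a),
      log2fc = tt$logFC,
      mean_log2cpm = ave,
      p_value = tt$PValue,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$adj_p <- bh_adjust_pooled(res$p_value)
  res$significant <- res$adj_p < alpha
  class(res) <- c("de_results", class(res))
  res
}

#' Benjamini-Hochberg adjustment pooled across all contrasts
#'
#' Standard step-up BH applied to the pooled p-value vector (all miRNAs in
#' all contrasts treated as one family).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust_pooled <- function(p) {
  if (any(is.na(p) | is.nan(p))) stop("NaN/NA p-value in input")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression selection rule
#'
#' A miRNA is called DE iff its mean log2 CPM exceeds \code{min_log2cpm},
#' it has at least one significant contrast, and either some significant
#' contrast has \code{|log2FC| > min_abs_lfc} or it has at least
#' \code{min_sig_contrasts} significant contrasts.
#'
#' @param results a \code{de_results} data.frame (from
#'   \code{\link{fit_pairwise_de}} or equivalent columns).
#' @param min_log2cpm expression gate on the overall mean log2 CPM (strict).
#' @param min_abs_lfc absolute log2 fold-change threshold (strict).
#' @param min_sig_contrasts alternative route: number of significant
#'   contrasts.
#' @return The input with an \code{is_de} column added (constant within
#'   miRNA); attribute \code{de_mirnas} carries the selected name set.
#' @export
select_de <- function(results, min_log2cpm = 5, min_abs_lfc = 1,
                      min_sig_contrasts = 3L) {
  sp <- split(seq_len(nrow(results)), results$mirna)
  de_set <- character(0)
  is_de <- logical(nrow(results))
  for (m in names(sp)) {
    i <- sp[[m]]
    sig <- results$significant[i]
    expr_ok <- mean(results$mean_log2cpm[i]) > min_log2cpm
    big_fc <- any(sig & abs(results$log2fc[i]) > min_abs_lfc)
    de <- expr_ok && any(sig) && (big_fc || sum(sig) >= min_sig_contrasts)
    is_de[i] <- de
    if (de) de_set <- c(de_set, m)
  }
  results$is_de <- is_de
  attr(results, "de_mirnas") <- sort(de_set)
  results
}
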