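#' Exclude qPCR samples with unconfident detection
#'
#' A sample is excluded iff its mean Cq across all assays is strictly above
#' \code{max_mean_cq} (late amplification throughout indicates too little
#' input miRNA for confident quantification).
#'
#' @param cq Cq matrix (assay x sample), no missing values.
#' @param max_mean_cq exclusion threshold on the per-sample mean Cq.
#' @return list with \code{retained} (sample IDs) and \code{log}
#'   (data.frame sample_id, mean_cq, excluded).
#' @export
exclude_cq_outliers <- function(cq, max_mean_cq = 25) {
  if (any(is.na(cq)))
    stop("missing Cq values are not supported; resolve non-detects upstream")
  m <- colMeans(cq)
  excluded <- m > max_mean_cq
  list(retained = colnames(cq)[!excluded],
       log = data.frame(sample_id = colnames(cq), mean_cq = as.numeric(m),
                        excluded = excluded, row.names = NULL,
                        stringsAsFactors = FALSE))
}

#' Relative expression normalized to a reference assay
#'
#' \code{EXP = Cq(reference) - Cq(target)} per sample per target, assuming
#' 100 percent amplification efficiency (one Cq unit = one log2 unit). The
#' reference's own EXP is 0 everywhere.
#'
#' @param cq Cq matrix (assay x sample).
#' @param reference reference assay name (default the normalization control
#'   miR-30e-5p).
#' @return EXP matrix with the same dimensions as \code{cq}.
#' @export
relative_expression <- function(cq, reference = "miR-30e-5p") {
  i <- stop_missing_mirna(rownames(cq), reference, "relative_expression")
  if (any(is.na(cq[i, ])))
    stop(sprintf("reference assay '%s' missing in some sample", reference))
  ref <- cq[i, ]
  out <- -sweep(cq, 2, ref)      # Cq(ref) - Cq(target)
  dimnames(out) <- dimnames(cq)
  out
}

#' NormFinder reference-gene stability
#'
#' Model-based variance decomposition of candidate reference assays on the
#' log2-abundance scale (Cq sign-flipped): per assay and group, the
#' intra-group variance is estimated from per-sample gene-centered
#' residuals and bias-corrected across assays; the inter-group effect is
#' the gene-centered group mean deviation, shrunk toward zero by its
#' estimated signal-to-noise ratio. The stability value is the group
#' average of |shrunken inter-group effect| + sqrt(intra-group variance /
#' group size); lower values indicate more stable assays.
#'
#' With only two candidate assays the intra-group bias correction is not
#' identifiable (the published estimator divides by k - 2); the raw
#' residual variance is used instead, documented here.
#'
#' @param cq Cq matrix (assay x sample), >= 2 assays.
#' @param groups group label per sample; >= 2 groups with >= 2 samples
#'   each.
#' @return data.frame with \code{assay}, \code{intra_sd},
#'   \code{inter_effect}, \code{stability}, sorted by increasing
#'   (= improving) stability.
#' @export
normfinder_stability <- function(cq, groups) {
  k <- nrow(cq)
  if (k < 2) stop("need at least 2 candidate assays")
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least 2 groups")
  n_i <- table(groups)[gl]
  if (any(n_i < 2)) stop("every group needs at least 2 samples (variance inestimable)")

  y <- -cq                                   # log2 abundance scale
  d <- sweep(y, 2, colMeans(y))              # remove per-sample level
  z <- matrix(0, k, length(gl), dimnames = list(rownames(cq), gl))
  s2 <- matrix(0, k, length(gl), dimnames = list(rownames(cq), gl))
  for (g in gl) {
    sub <- d[, groups == g, drop = FALSE]
    z[, g] <- rowMeans(sub)
    s2[, g] <- apply(sub, 1, stats::var)
  }
  # bias-corrected intra-group variances (gene-centering couples genes)
  sig2 <- matrix(0, k, length(gl), dimnames = dimnames(s2))
  for (g in gl) {
    if (k > 2) sig2[, g] <- pmax((k / (k - 2)) *
                                   (s2[, g] - sum(s2[, g]) / (k * (k - 1))), 0)
    else sig2[, g] <- s2[, g]
  }
  # inter-group effects, centered per assay, shrunk by signal-to-noise
  cgi <- z - rowMeans(z)
  samp_var <- sweep(sig2, 2, as.numeric(n_i), "/")
  m <- length(gl)
  gamma2 <- max(sum(cgi^2) / ((m - 1) * max(k - 1, 1)) - mean(samp_var), 0)
  shrunk <- if (gamma2 > 0) cgi * gamma2 / (gamma2 + samp_var) else cgi * 0
  stability <- rowMeans(abs(shrunk) + sqrt(samp_var))

  out <- data.frame(assay = rownames(cq),
                    intra_sd = rowMeans(sqrt(sig2)),
                    inter_effect = rowMeans(abs(shrunk)),
                    stability = as.numeric(stability),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$stability), ]
}

#' Concordance between qPCR- and sequencing-based relative expression
#'
#' Ordinary least-squares R-squared and Spearman rank correlation between
#' matched per-sample relative-expression values from the two platforms.
#'
#' @param exp_cpm named numeric: sequencing-based relative expression
#'   (log2CPM(target) - log2CPM(reference)) per sample.
#' @param exp_pcr named numeric: qPCR-based EXP values per sample.
#' @return list with \code{r_squared}, \code{spearman_rho},
#'   \code{spearman_p}, \code{n}, and \code{pairs} (the matched table).
#' @export
concordance <- function(exp_cpm, exp_pcr) {
  common <- intersect(names(exp_cpm), names(exp_pcr))
  if (length(common) < 3)
    stop("need at least 3 matched samples for concordance")
  x <- exp_cpm[common]; y <- exp_pcr[common]
  fit <- stats::lm(y ~ x)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  # a perfect fit is a legitimate input here; silence summary()'s note
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value,
       n = length(common),
       pairs = data.frame(sample_id = common, exp_cpm = as.numeric(x),
                          exp_pcr = as.numeric(y), stringsAsFactors = FALSE))
}
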