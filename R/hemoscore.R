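#' Lipemia-independent spectrophotometric hemolysis score
#'
#' \code{HS = (A414 - A385) + 0.16 * A385}, from 1-mm-path UV-vis
#' absorbances at the free-hemoglobin peak (414 nm) and at 385 nm. Slightly
#' negative absorbances (blank subtraction) trigger a warning but are
#' computed anyway.
#'
#' @param A414,A385 finite absorbance values (vectorized).
#' @return Hemolysis score(s).
#' @export
hemolysis_score <- function(A414, A385) {
  if (!all(is.finite(A414)) || !all(is.finite(A385)))
    stop("absorbances must be finite")
  if (any(A414 < 0) || any(A385 < 0))
    warning("negative absorbance encountered; computing the score anyway")
  (A414 - A385) + 0.16 * A385
}

#' Sequencing-based miRNA hemolysis ratio
#'
#' \code{log2CPM(miR-451a) - log2CPM(miR-23a-3p)} per sample: the
#' RBC-enriched miR-451a rises with hemolysis while miR-23a-3p is
#' hemolysis-insensitive, so larger values indicate more hemolysis.
#'
#' @param log2cpm log2 CPM matrix containing both sentinel miRNAs.
#' @param samples sample IDs (default: all columns).
#' @return Named numeric vector of ratios.
#' @export
seq_hemolysis_ratio <- function(log2cpm, samples = colnames(log2cpm)) {
  i451 <- stop_missing_mirna(rownames(log2cpm), "miR-451a",
                             "seq_hemolysis_ratio")
  i23 <- stop_missing_mirna(rownames(log2cpm), "miR-23a-3p",
                            "seq_hemolysis_ratio")
  v <- log2cpm[i451, samples] - log2cpm[i23, samples]
  stats::setNames(as.numeric(v), samples)
}

#' qPCR-based miRNA hemolysis indicator
#'
#' \code{dCq(miR-23a-3p - miR-451a) = Cq(miR-23a-3p) - Cq(miR-451a)};
#' larger values indicate relatively more miR-451a, hence more hemolysis.
#'
#' @param cq Cq matrix (assay x sample) containing both assays.
#' @param samples sample IDs (default: all columns).
#' @return Named numeric vector of dCq values.
#' @export
qpcr_hemolysis_dcq <- function(cq, samples = colnames(cq)) {
  i23 <- stop_missing_mirna(rownames(cq), "miR-23a-3p", "qpcr_hemolysis_dcq")
  i451 <- stop_missing_mirna(rownames(cq), "miR-451a", "qpcr_hemolysis_dcq")
  v <- cq[i23, samples] - cq[i451, samples]
  stats::setNames(as.numeric(v), samples)
}

#' RBC-Platelet miRNA ratio from qPCR data
#'
#' Absolute difference between the mean Cq of the RBC-related trio
#' (miR-451a, miR-92a-3p, miR-16-5p) and the mean Cq of the
#' platelet-related quartet (miR-223-3p, miR-126-3p, miR-21-5p,
#' miR-150-5p). A shift in this ratio indicates origin-composition bias.
#'
#' @param cq Cq matrix (assay x sample); all seven assays must be present.
#' @param samples sample IDs (default: all columns).
#' @param rbc,platelet assay name sets forming the two panels.
#' @return Named numeric vector of per-sample ratios.
#' @export
rbc_platelet_ratio <- function(cq, samples = colnames(cq),
                               rbc = c("miR-451a", "miR-92a-3p", "miR-16-5p"),
                               platelet = c("miR-223-3p", "miR-126-3p",
                                            "miR-21-5p", "miR-150-5p")) {
  ir <- vapply(rbc, function(a)
    stop_missing_mirna(rownames(cq), a, "rbc_platelet_ratio"), 0L)
  ip <- vapply(platelet, function(a)
    stop_missing_mirna(rownames(cq), a, "rbc_platelet_ratio"), 0L)
  v <- abs(colMeans(cq[ir, samples, drop = FALSE]) -
             colMeans(cq[ip, samples, drop = FALSE]))
  stats::setNames(as.numeric(v), samples)
}

#' Origin-fraction decomposition of normalized expression
#'
#' Per group, the fraction of summed (TMM-)normalized CPM attributable to
#' each origin panel (RBC-derived, platelet-derived, hemolysis-susceptible,
#' other), plus the within-panel composition vectors for the RBC and
#' platelet panels.
#'
#' @param norm_cpm normalized CPM matrix (miRNA x sample), e.g. from
#'   \code{\link{tmm_cpm}}.
#' @param groups group label per sample.
#' @param panels origin panels; resolved against the matrix rows via
#'   \code{\link{resolve_panels}}.
#' @return list with \code{fractions} (group x category matrix, rows sum
#'   to 1), \code{rbc_composition} and \code{platelet_composition}
#'   (within-panel fraction matrices), and \code{panels} (as resolved).
#' @export
origin_fractions <- function(norm_cpm, groups,
                             panels = default_origin_panels()) {
  res <- resolve_panels(panels, rownames(norm_cpm))
  if (length(intersect(res$rbc, res$platelet)) > 0)
    stop("origin panels overlap after conflict resolution")
  gl <- unique(groups)
  cat_of <- c("rbc", "platelet", "hemolysis_susceptible", "other")
  fractions <- matrix(0, length(gl), length(cat_of),
                      dimnames = list(gl, cat_of))
  comp <- function(panel, g) {
    v <- rowSums(norm_cpm[panel, groups == g, drop = FALSE])
    if (sum(v) == 0) return(v)
    v / sum(v)
  }
  rbc_comp <- matrix(0, length(gl), length(res$rbc),
                     dimnames = list(gl, res$rbc))
  plt_comp <- matrix(0, length(gl), length(res$platelet),
                     dimnames = list(gl, res$platelet))
  for (g in gl) {
    tot <- sum(norm_cpm[, groups == g, drop = FALSE])
    for (cat in cat_of) {
      rows <- res[[cat]]
      fractions[g, cat] <-
        sum(norm_cpm[rows, groups == g, drop = FALSE]) / tot
    }
    if (length(res$rbc) > 0) rbc_comp[g, ] <- comp(res$rbc, g)
    if (length(res$platelet) > 0) plt_comp[g, ] <- comp(res$platelet, g)
  }
  list(fractions = fractions, rbc_composition = rbc_comp,
       platelet_composition = plt_comp, panels = res)
}
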