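#' Shannon alpha diversity of a CPM vector
#'
#' \eqn{H = -\sum p_i \ln p_i} over positive entries, with \eqn{p_i} the
#' relative abundance; natural logarithm. Delegates to
#' \code{vegan::diversity}, the standard alpha-diversity implementation.
#'
#' @param x nonnegative abundance (CPM) vector with at least one positive
#'   entry.
#' @return The Shannon index (>= 0).
#' @export
shannon_index <- function(x) {
  if (any(x < 0) || all(x == 0))
    stop("diversity undefined: need a nonnegative vector with a positive entry")
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Per-sample diversity summary
#'
#' @param cpm CPM matrix (miRNA x sample).
#' @param threshold per-sample detection threshold (CPM strictly above).
#' @return data.frame with \code{sample_id}, \code{shannon},
#'   \code{detected}.
#' @export
diversity_summary <- function(cpm, threshold = 2) {
  data.frame(sample_id = colnames(cpm),
             shannon = apply(cpm, 2, shannon_index),
             detected = detected_per_sample(cpm, threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Number of detected miRNAs per sample
#'
#' @param cpm CPM matrix.
#' @param threshold detection threshold (CPM strictly above).
#' @return Named integer vector of per-sample detected counts.
#' @export
detected_per_sample <- function(cpm, threshold = 2) {
  colSums(cpm > threshold)
}

#' Fraction of group expression captured by the top-N miRNAs
#'
#' Ranks miRNAs by mean CPM within the group and returns the summed mean
#' CPM of the top \code{n} divided by the total. If fewer than \code{n}
#' miRNAs are present, all are used and the result carries attribute
#' \code{truncated = TRUE}.
#'
#' @param cpm CPM matrix.
#' @param groups group label per sample (aligned with columns).
#' @param group which group to summarize.
#' @param n number of top miRNAs.
#' @return Fraction in [0, 1].
#' @export
topn_fraction <- function(cpm, groups, group, n = 20L) {
  sel <- groups == group
  if (!any(sel)) stop(sprintf("group '%s' has no samples", group))
  m <- rowMeans(cpm[, sel, drop = FALSE])
  truncated <- length(m) < n
  top <- sort(m, decreasing = TRUE)[seq_len(min(n, length(m)))]
  out <- sum(top) / sum(m)
  if (truncated) attr(out, "truncated") <- TRUE
  out
}

#' Overlap partition of per-group detected miRNA sets
#'
#' Computes, for every region of the Venn partition over the groups, the
#' number of miRNAs detected in exactly that combination of groups.
#' Detection within a group follows the expression-filter rule scaled to
#' the group: CPM strictly above \code{min_cpm} in at least
#' \code{min_samples} samples of the group.
#'
#' @param cpm CPM matrix.
#' @param groups group label per sample.
#' @param min_cpm detection CPM threshold.
#' @param min_samples per-group sample support.
#' @return list with \code{sets} (per-group detected name sets),
#'   \code{regions} (named integer vector; names like \code{"A&B"}), and
#'   \code{union_size}.
#' @export
group_overlap <- function(cpm, groups, min_cpm = 2, min_samples = 2L) {
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least two groups")
  sets <- lapply(gl, function(g) {
    sub <- cpm[, groups == g, drop = FALSE]
    rownames(sub)[rowSums(sub > min_cpm) >= min_samples]
  })
  names(sets) <- gl
  overlap_partition(sets)
}

#' @rdname group_overlap
#' @param sets a named list of character sets (used directly instead of
#'   deriving detection from a CPM matrix).
#' @export
overlap_partition <- function(sets) {
  gl <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, gl))
  key <- apply(member, 1, function(r) paste(gl[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(gl), function(k)
    utils::combn(gl, k, paste, collapse = "&", simplify = FALSE)))
  regions <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  list(sets = sets, regions = regions, union_size = length(universe))
}

#' PCA of scaled log2 CPM profiles
#'
#' Centers and unit-variance scales each miRNA across samples, then
#' performs a singular value decomposition (via \code{prcomp}) of the
#' sample x miRNA matrix. Constant rows are dropped with a warning. Signs
#' are fixed so that the largest-magnitude loading of each component is
#' positive, making results invariant to sample order up to permutation.
#'
#' @param log2cpm log2 CPM matrix (miRNA x sample), >= 3 samples.
#' @param n_components number of components to return (truncated to the
#'   matrix rank with a warning).
#' @return list with \code{scores} (sample x PC), \code{loadings}
#'   (miRNA x PC), \code{var_frac} (variance fractions over the full rank,
#'   summing to 1).
#' @export
pca_profiles <- function(log2cpm, n_components = 10L) {
  if (ncol(log2cpm) < 3) stop("PCA requires at least 3 samples")
  const <- apply(log2cpm, 1, function(r) stats::var(r) == 0)
  if (any(const)) {
    warning(sprintf("dropping %d constant miRNA row(s) before scaling",
                    sum(const)))
    log2cpm <- log2cpm[!const, , drop = FALSE]
  }
  p <- stats::prcomp(t(log2cpm), center = TRUE, scale. = TRUE)
  rank <- sum(p$sdev > 1e-10)
  k <- min(n_components, rank)
  if (k < n_components)
    warning(sprintf("requested %d components, rank is %d: truncated",
                    n_components, rank))
  flip <- apply(p$rotation[, seq_len(k), drop = FALSE], 2, function(v)
    sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings, var_frac = var_frac)
}
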