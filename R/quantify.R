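#' Aggregate assigned reads into a count matrix and isomiR tallies
#'
#' Pools all isoforms of a miRNA into its count; tallies isoforms keyed by
#' exact read sequence. Per-sample miRNA-read percentage and unaligned
#' fraction are recorded into the metadata.
#'
#' @param assignments named list (one element per sample) of
#'   \code{\link{assign_reads}} outputs; names are sample IDs.
#' @param reference the \code{mirna_reference} used for assignment.
#' @param total_reads optional named vector of per-sample total (pre-mapping)
#'   read counts used for the miRNA-read percentage; defaults to the number
#'   of assigned+unassigned reads per sample.
#' @param metadata optional data.frame with \code{sample_id},
#'   \code{subject_id}, \code{group} to merge in.
#' @return A list of class \code{mirna_counts}: \code{counts} (miRNA x
#'   sample integer matrix), \code{samples} (metadata data.frame with
#'   \code{percent_mirna_reads}, \code{unaligned_fraction}), and
#'   \code{isomirs} (data.frame mirna, sequence, offset5, offset3,
#'   mismatches, one count column per sample).
#' @export
count_samples <- function(assignments, reference, total_reads = NULL,
                          metadata = NULL) {
  ids <- names(assignments)
  if (is.null(ids) || anyDuplicated(ids))
    stop("assignments must be a uniquely named list of samples")
  mirnas <- reference$mature$name
  counts <- matrix(0L, length(mirnas), length(ids),
                   dimnames = list(mirnas, ids))
  pct <- numeric(length(ids)); unal <- numeric(length(ids))
  tallies <- list()
  for (j in seq_along(ids)) {
    a <- assignments[[j]]
    hit <- !is.na(a$mirna)
    tab <- table(factor(a$mirna[hit], levels = mirnas))
    counts[, j] <- as.integer(tab)
    n_total <- if (!is.null(total_reads)) total_reads[[ids[j]]] else nrow(a)
    pct[j] <- if (n_total > 0) 100 * sum(hit) / n_total else 0
    unal[j] <- if (nrow(a) > 0) 100 * sum(!hit) / nrow(a) else 0
    if (any(hit)) {
      key <- paste(a$mirna[hit], a$read[hit], sep = "\r")
      t2 <- table(key)
      tallies[[ids[j]]] <- data.frame(key = names(t2),
                                      n = as.integer(t2),
                                      stringsAsFactors = FALSE)
    }
  }
  all_keys <- sort(unique(unlist(lapply(tallies, `[[`, "key"))))
  iso <- NULL
  if (length(all_keys) > 0) {
    parts <- strsplit(all_keys, "\r", fixed = TRUE)
    iso <- data.frame(mirna = vapply(parts, `[[`, "", 1L),
                      sequence = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
    for (id in ids) {
      v <- integer(length(all_keys))
      if (!is.null(tallies[[id]]))
        v[match(tallies[[id]]$key, all_keys)] <- tallies[[id]]$n
      iso[[id]] <- v
    }
  }
  samples <- data.frame(sample_id = ids, percent_mirna_reads = pct,
                        unaligned_fraction = unal, stringsAsFactors = FALSE)
  if (!is.null(metadata))
    samples <- merge(samples, metadata, by = "sample_id", sort = FALSE)
  out <- list(counts = counts, samples = samples, isomirs = iso)
  class(out) <- "mirna_counts"
  out
}

#' Remove potentially noisy miRNA rows
#'
#' A miRNA row is removed iff its mean count across samples is at most 2
#' \emph{and} it is absent (zero) in at least 90 percent of samples; all
#' other rows pass unchanged.
#'
#' @param counts miRNA x sample count matrix.
#' @param max_mean mean-count threshold (inclusive).
#' @param min_missing_frac zero-fraction threshold (inclusive).
#' @return The filtered count matrix.
#' @export
filter_noisy <- function(counts, max_mean = 2, min_missing_frac = 0.9) {
  stopifnot(ncol(counts) >= 1)
  noisy <- rowMeans(counts) <= max_mean &
    rowMeans(counts == 0) >= min_missing_frac
  counts[!noisy, , drop = FALSE]
}

#' Counts per million
#'
#' \code{CPM = count / library_size * 1e6} with library size the column sum
#' of the (post-noise-filter) matrix.
#'
#' @param counts miRNA x sample count matrix with nonzero library sizes.
#' @return CPM matrix of the same shape.
#' @export
cpm_matrix <- function(counts) {
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    stop(sprintf("zero library size for sample(s): %s",
                 paste(colnames(counts)[zero], collapse = ", ")))
  sweep(counts, 2, lib, "/") * 1e6
}

#' log2 CPM with a 1-CPM pseudocount
#'
#' @param counts count matrix, or a CPM matrix with \code{is_cpm = TRUE}.
#' @param is_cpm set TRUE if \code{counts} is already on the CPM scale.
#' @return \code{log2(CPM + 1)} matrix, bounded below at 0.
#' @export
log2cpm_matrix <- function(counts, is_cpm = FALSE) {
  x <- if (is_cpm) counts else cpm_matrix(counts)
  log2(x + 1)
}

#' Expression filter
#'
#' Retains miRNAs with CPM strictly above \code{min_cpm} in at least
#' \code{min_samples} samples.
#'
#' @param cpm CPM matrix.
#' @param min_cpm CPM threshold (strict).
#' @param min_samples minimum number of samples meeting the threshold.
#' @return Character vector of retained miRNA names.
#' @export
expression_filter <- function(cpm, min_cpm = 2, min_samples = 10L) {
  keep <- rowSums(cpm > min_cpm) >= min_samples
  rownames(cpm)[keep]
}

#' Isoform prevalence filter and major-isoform report
#'
#' An isoform (unique read sequence) is retained iff its parent miRNA
#' passes the expression criterion (CPM > \code{min_cpm} in at least
#' \code{min_samples} samples) and the isoform's mean read count across
#' samples is strictly above \code{min_mean_count}. The major-isoform
#' report lists retained isoforms whose pooled count exceeds
#' \code{major_frac} of the parent miRNA's pooled count.
#'
#' @param isomirs isomiR tally data.frame from \code{\link{count_samples}}
#'   (columns \code{mirna}, \code{sequence}, then one count column per
#'   sample).
#' @param cpm CPM matrix of the parent miRNAs.
#' @param min_cpm,min_samples parent expression criterion.
#' @param min_mean_count isoform mean-count threshold (strict).
#' @param major_frac fraction of parent expression defining a major isoform.
#' @return list with \code{retained} (filtered tally data.frame) and
#'   \code{major} (major-isoform report with \code{fraction_of_parent}).
#' @export
isoform_filter <- function(isomirs, cpm, min_cpm = 2, min_samples = 10L,
                           min_mean_count = 10, major_frac = 0.1) {
  stopifnot(is.data.frame(isomirs))
  cnt_cols <- setdiff(colnames(isomirs),
                      c("mirna", "sequence", "offset5", "offset3",
                        "mismatches", "classes"))
  if (!all(isomirs$mirna %in% rownames(cpm)))
    stop("isoform references a miRNA absent from the expression matrix")
  parents_ok <- expression_filter(cpm, min_cpm, min_samples)
  m <- as.matrix(isomirs[, cnt_cols, drop = FALSE])
  keep <- isomirs$mirna %in% parents_ok & rowMeans(m) > min_mean_count
  retained <- isomirs[keep, , drop = FALSE]

  pooled_iso <- rowSums(as.matrix(retained[, cnt_cols, drop = FALSE]))
  parent_tot <- tapply(rowSums(m), isomirs$mirna, sum)
  frac <- pooled_iso / as.numeric(parent_tot[retained$mirna])
  major <- retained[frac > major_frac, , drop = FALSE]
  if (nrow(major) > 0)
    major$fraction_of_parent <- frac[frac > major_frac]
  list(retained = retained, major = major)
}

#' Sample QC gate
#'
#' Excludes samples whose miRNA-read percentage falls strictly below
#' \code{min_mirna_pct}; samples with an unaligned-read fraction strictly
#' above \code{max_unaligned} are flagged, and also excluded when
#' \code{strict = TRUE}.
#'
#' @param samples sample metadata data.frame with \code{sample_id},
#'   \code{percent_mirna_reads}, \code{unaligned_fraction}.
#' @param min_mirna_pct miRNA-read percentage threshold.
#' @param max_unaligned unaligned percentage threshold.
#' @param strict exclude (not just flag) high-unaligned samples.
#' @return list with \code{retained} (character sample IDs) and
#'   \code{exclusions} (data.frame sample_id, reason, excluded).
#' @export
sample_qc_gate <- function(samples, min_mirna_pct = 15, max_unaligned = 50,
                          strict = FALSE) {
  low <- samples$percent_mirna_reads < min_mirna_pct
  high <- samples$unaligned_fraction > max_unaligned
  reason <- character(nrow(samples))
  reason[high] <- "high_unaligned"
  reason[low] <- "low_mirna_fraction"   # low-miRNA rule takes precedence
  excluded <- low | (strict & high)
  log <- data.frame(sample_id = samples$sample_id[low | high],
                    reason = reason[low | high],
                    excluded = excluded[low | high],
                    stringsAsFactors = FALSE)
  list(retained = samples$sample_id[!excluded], exclusions = log)
}
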