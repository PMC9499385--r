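# Hairpin-context alignment of preprocessed reads against mature miRNAs.
#
# A candidate placement anchors the read on a mature sequence with a 5' end
# offset o5 (positive = 5' trim, negative = 5' extension) and the implied 3'
# offset o3 (negative = trim, positive = extension), both bounded by
# max_shift. The read is compared gaplessly against the hairpin; mismatches
# are counted only inside the overlap with the canonical mature region --
# extended bases are judged against hairpin context by the classifier, not
# the aligner. Best candidate: fewest internal mismatches, then smallest
# |o5| + |o3|, then lexicographically smallest miRNA name.

# Precompute per-mature hairpin context used by assignment/classification.
reference_index <- function(reference, max_shift = 3L) {
  mat <- reference$mature
  hp <- reference$hairpin$sequence[match(mat$hairpin_id, reference$hairpin$id)]
  list(name = mat$name, start = mat$start, end = mat$end,
       len = mat$end - mat$start, hairpin = hp, order = order(mat$name),
       max_shift = as.integer(max_shift))
}

# Trim-variant dictionary: every pure-trim templated variant (5' trim t5 in
# 0..max_shift, 3' trim t3 in -max_shift..0) of every mature sequence,
# hashed by sequence. Any zero-internal-mismatch placement of a read
# decomposes as (5' extension bases | trim-variant core | 3' extension
# bases), so looking up all (p, q) strip-offs of a read against this
# dictionary enumerates exactly the mismatch-free candidates -- including
# non-templated extensions, whose bases lie outside the mature overlap.
trim_dictionary <- function(idx) {
  ms <- idx$max_shift
  grid <- expand.grid(t5 = 0:ms, t3 = -(0:ms), KEEP.OUT.ATTRS = FALSE)
  n <- length(idx$name)
  rows <- nrow(grid)
  seqs <- character(n * rows)
  mirna <- character(n * rows)
  o5 <- integer(n * rows); o3 <- integer(n * rows)
  pos <- 0L
  for (k in seq_len(n)) {
    v <- substr(idx$hairpin[k], idx$start[k] + grid$t5 + 1L,
                idx$end[k] + grid$t3)
    ii <- pos + seq_len(rows)
    seqs[ii] <- v; mirna[ii] <- idx$name[k]
    o5[ii] <- grid$t5; o3[ii] <- grid$t3
    pos <- pos + rows
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    env[[seqs[i]]] <- c(env[[seqs[i]]], i)
  }
  list(env = env, mirna = mirna, o5 = o5, o3 = o3)
}

# All zero-mismatch candidates for one read via dictionary lookups; returns
# the tie-break winner or NULL.
dict_best <- function(read, dict, ms) {
  L <- nchar(read)
  best <- NULL
  for (p in 0:ms) {
    for (q in 0:ms) {
      if (L - p - q < 1L) next
      core <- substr(read, p + 1L, L - q)
      hits <- dict$env[[core]]
      if (is.null(hits)) next
      for (i in hits) {
        t5 <- dict$o5[i]; t3 <- dict$o3[i]
        if ((p > 0L && t5 != 0L) || (q > 0L && t3 != 0L)) next
        o5 <- t5 - p; o3 <- t3 + q
        shift <- abs(o5) + abs(o3)
        if (is.null(best) || shift < best$shift ||
            (shift == best$shift && dict$mirna[i] < best$mirna))
          best <- list(mirna = dict$mirna[i], o5 = o5, o3 = o3,
                       mismatches = 0L, shift = shift)
      }
    }
  }
  best
}

# Score one read against every placement of one mature; returns the best
# candidate row or NULL.
score_against <- function(read, idx, k, max_mismatch) {
  L <- nchar(read)
  s <- idx$start[k]; e <- idx$end[k]
  hp <- idx$hairpin[k]; hplen <- nchar(hp)
  ms <- idx$max_shift
  rraw <- charToRaw(read)
  best <- NULL
  for (o5 in -ms:ms) {
    o3 <- (s + o5 + L) - e
    if (abs(o3) > ms) next
    a <- s + o5          # 0-based read start on hairpin
    b <- a + L           # 0-based exclusive end
    # overlap of read with the canonical mature region, in read coordinates
    ov_lo <- max(a, s) - a + 1L
    ov_hi <- min(b, e) - a
    if (ov_hi < ov_lo) next
    ha <- max(a, 0L); hb <- min(b, hplen)
    if (hb <= ha) next
    win <- charToRaw(substr(hp, ha + 1L, hb))
    roff <- ha - a                     # read bases clipped off the hairpin
    rcmp <- rraw[(roff + 1L):(roff + (hb - ha))]
    neq <- rcmp != win
    # positions (read coords) of the mature-overlap region within rcmp
    rel <- (ov_lo:ov_hi) - roff
    mm <- sum(neq[rel])
    if (mm > max_mismatch) next
    shift <- abs(o5) + abs(o3)
    if (is.null(best) || mm < best$mismatches ||
        (mm == best$mismatches && shift < best$shift)) {
      best <- list(mirna = idx$name[k], o5 = o5, o3 = o3,
                   mismatches = mm, shift = shift)
    }
  }
  best
}

#' Assign preprocessed reads to mature miRNAs
#'
#' Gapless hairpin-context alignment with bounded end offsets and internal
#' mismatches. Deterministic tie-break: fewest internal mismatches, then
#' smallest total absolute offset, then lexicographically smallest miRNA
#' name. Reads matching nothing within bounds are reported unaligned.
#'
#' @param reads character vector of insert sequences (16-28 nt, ACGTN).
#' @param reference a \code{mirna_reference}.
#' @param max_shift maximum absolute 5'/3' end offset.
#' @param max_mismatch maximum internal mismatches inside the mature overlap.
#' @return data.frame with one row per read: \code{read}, \code{mirna}
#'   (\code{NA} if unaligned), \code{offset5}, \code{offset3},
#'   \code{mismatches}.
#' @export
assign_reads <- function(reads, reference, max_shift = 3L, max_mismatch = 2L) {
  if (length(reads) > 0 && any(grepl("[^ACGTN]", reads)))
    stop("reads contain characters outside the ACGTN alphabet")
  idx <- reference_index(reference, max_shift)
  dict <- trim_dictionary(idx)
  uq <- unique(reads)
  n <- length(uq)
  res <- data.frame(read = uq, mirna = NA_character_,
                    offset5 = NA_integer_, offset3 = NA_integer_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  name_order <- idx$order
  for (i in seq_len(n)) {
    best <- dict_best(uq[i], dict, idx$max_shift)
    if (is.null(best)) {
      # no mismatch-free placement anywhere: full scan with mismatches
      for (k in name_order) { # lexicographic order => first win is the name tie-break
        cand <- score_against(uq[i], idx, k, max_mismatch)
        if (is.null(cand)) next
        if (is.null(best) || cand$mismatches < best$mismatches ||
            (cand$mismatches == best$mismatches && cand$shift < best$shift))
          best <- cand
      }
    }
    if (!is.null(best)) {
      res$mirna[i] <- best$mirna
      res$offset5[i] <- best$o5
      res$offset3[i] <- best$o3
      res$mismatches[i] <- best$mismatches
    }
  }
  res[match(reads, uq), , drop = FALSE]
}

#' @rdname assign_reads
#' @param read a single read sequence.
#' @return \code{assign_read}: a one-row data.frame (see
#'   \code{\link{assign_reads}}).
#' @export
assign_read <- function(read, reference, max_shift = 3L, max_mismatch = 2L) {
  stopifnot(length(read) == 1L)
  assign_reads(read, reference, max_shift, max_mismatch)
}

#' Classify an assigned read into the isomiR taxonomy
#'
#' Computes the isoform class labels of a read relative to its assigned
#' canonical mature sequence: \code{canonical} (exact), \code{trim3} /
#' \code{trim5} (shortened ends), \code{ext3_templated} /
#' \code{ext5_templated} (extension bases all matching the hairpin
#' context), \code{ext3_nontemplated} / \code{ext5_nontemplated} (any
#' extension base deviating from, or lying beyond, the hairpin), and
#' \code{polymorphic} (internal single-nucleotide differences inside the
#' mature overlap). Labels other than \code{canonical} are non-exclusive.
#'
#' @param assignment one row of \code{\link{assign_reads}} output (must be
#'   aligned).
#' @param reference the \code{mirna_reference} used for assignment.
#' @return A list of class \code{isomir_annotation}: \code{mirna_name},
#'   \code{read_sequence}, \code{offset5}, \code{offset3},
#'   \code{ext5_templated}, \code{ext3_templated} (NA when no such
#'   extension), \code{internal_mismatches} (data.frame position/ref/read,
#'   positions 1-based on the read), \code{class_labels}.
#' @export
classify_isomir <- function(assignment, reference) {
  if (is.na(assignment$mirna))
    stop("cannot classify an unaligned read")
  k <- match(assignment$mirna, reference$mature$name)
  if (is.na(k)) stop("assignment references a miRNA absent from the reference")
  read <- assignment$read
  o5 <- assignment$offset5; o3 <- assignment$offset3
  s <- reference$mature$start[k]; e <- reference$mature$end[k]
  hp <- reference$hairpin$sequence[match(reference$mature$hairpin_id[k],
                                         reference$hairpin$id)]
  hplen <- nchar(hp)
  L <- nchar(read)
  if (L != (e + o3) - (s + o5))
    stop("assignment offsets inconsistent with read length")

  labels <- character(0)
  ext5 <- NA; ext3 <- NA

  # 5' end
  if (o5 > 0) labels <- c(labels, "trim5")
  if (o5 < 0) {
    k5 <- -o5
    if (s + o5 < 0) ext5 <- FALSE    # runs off the hairpin: non-templated
    else ext5 <- substr(read, 1L, k5) == substr(hp, s + o5 + 1L, s)
    labels <- c(labels, if (ext5) "ext5_templated" else "ext5_nontemplated")
  }
  # 3' end
  if (o3 < 0) labels <- c(labels, "trim3")
  if (o3 > 0) {
    if (e + o3 > hplen) ext3 <- FALSE
    else ext3 <- substr(read, L - o3 + 1L, L) == substr(hp, e + 1L, e + o3)
    labels <- c(labels, if (ext3) "ext3_templated" else "ext3_nontemplated")
  }

  # internal mismatches inside the mature overlap
  a <- s + o5
  ov_lo <- max(a, s) - a + 1L
  ov_hi <- min(a + L, e) - a
  mm <- data.frame(position = integer(0), ref_base = character(0),
                   read_base = character(0), stringsAsFactors = FALSE)
  if (ov_hi >= ov_lo) {
    rb <- strsplit(substr(read, ov_lo, ov_hi), "")[[1]]
    hb <- strsplit(substr(hp, a + ov_lo, a + ov_hi), "")[[1]]
    d <- which(rb != hb)
    if (length(d) > 0)
      mm <- data.frame(position = ov_lo + d - 1L, ref_base = hb[d],
                       read_base = rb[d], stringsAsFactors = FALSE)
  }
  if (nrow(mm) > 0) labels <- c(labels, "polymorphic")
  if (o5 == 0 && o3 == 0 && nrow(mm) == 0) labels <- "canonical"

  ann <- list(mirna_name = assignment$mirna, read_sequence = read,
              offset5 = o5, offset3 = o3,
              ext5_templated = ext5, ext3_templated = ext3,
              internal_mismatches = mm, class_labels = labels)
  class(ann) <- "isomir_annotation"
  ann
}

#' @export
print.isomir_annotation <- function(x, ...) {
  cat(sprintf("isomiR of %s: offsets (%+d, %+d), classes: %s\n",
              x$mirna_name, x$offset5, x$offset3,
              paste(x$class_labels, collapse = ", ")))
  invisible(x)
}
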