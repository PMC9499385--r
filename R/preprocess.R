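#' Locate and trim the 3' adapter from a read sequence
#'
#' Finds the leftmost occurrence of the adapter and truncates the read
#' there. Full-length internal occurrences may carry mismatches up to
#' \code{floor(error_rate * adapter_length)}; partial matches are accepted
#' only at the 3' terminus, with at least \code{min_overlap} bases and a
#' mismatch budget of \code{floor(error_rate * overlap)}. Reads without
#' adapter evidence are rejected (returned as \code{NA}): an untrimmed read
#' retains its 3' randomized bases at unknown positions and cannot be
#' classified downstream.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum 3'-terminal partial-match length.
#' @param error_rate allowed mismatch fraction (mismatches only, no indels).
#' @return character vector: trimmed sequences, \code{NA} where no adapter
#'   was found. Zero-length results are returned as \code{""}.
#' @export
trim_adapter <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 6L, error_rate = 0.1) {
  stopifnot(nchar(adapter) >= 1)
  pos <- adapter_position(reads, adapter, min_overlap, error_rate)
  out <- substr(reads, 1L, ifelse(is.na(pos), 0L, pos - 1L))
  out[is.na(pos)] <- NA_character_
  out
}

# Leftmost adapter start position (1-based) per read, NA if not found.
adapter_position <- function(reads, adapter, min_overlap = 6L,
                             error_rate = 0.1) {
  alen <- nchar(adapter)
  # fast path: exact full-length occurrence
  pos <- regexpr(adapter, reads, fixed = TRUE)
  pos <- ifelse(pos > 0, as.integer(pos), NA_integer_)
  todo <- which(is.na(pos) | pos > 1L)
  if (length(todo) > 0) {
    araw <- charToRaw(adapter)
    for (i in todo) {
      r <- reads[i]
      L <- nchar(r)
      rraw <- charToRaw(r)
      best <- if (is.na(pos[i])) L + 1L else pos[i]
      for (s in seq_len(min(best - 1L, L - min_overlap + 1L))) {
        ov <- min(alen, L - s + 1L)
        mm <- sum(rraw[s:(s + ov - 1L)] != araw[seq_len(ov)])
        if (mm <= floor(error_rate * ov)) { best <- s; break }
      }
      pos[i] <- if (best <= L) best else NA_integer_
    }
  }
  pos
}

#' Remove randomized bases from both ends of adapter-trimmed reads
#'
#' The library protocol ligates 4 randomized bases to each end of the
#' insert; after adapter removal they are stripped positionally. Reads too
#' short to contain any insert (length < 2n + 1) are rejected.
#'
#' @param reads character vector of adapter-trimmed sequences.
#' @param n number of randomized bases on each end.
#' @return character vector with \code{NA} for rejected reads.
#' @export
strip_random_bases <- function(reads, n = 4L) {
  L <- nchar(reads)
  out <- ifelse(!is.na(reads) & L >= 2L * n + 1L,
                substr(reads, n + 1L, L - n), NA_character_)
  out
}

#' Insert length gate
#'
#' @param reads character vector of stripped insert sequences.
#' @param min,max inclusive length bounds.
#' @return logical vector: TRUE where the read passes.
#' @export
length_gate <- function(reads, min = 16L, max = 28L) {
  L <- nchar(reads)
  !is.na(reads) & L >= min & L <= max
}

#' Preprocess a small-RNA FASTQ file
#'
#' Applies the read-cleaning cascade in protocol order: 3' adapter trimming
#' (reads without adapter evidence discarded), removal of the randomized
#' bases from both ends, and the insert length gate. Surviving reads are
#' written to \code{out_path} with their quality strings subset to the
#' retained bases.
#'
#' @param in_path input FASTQ (optionally gzipped).
#' @param out_path output FASTQ path, or \code{NULL} to skip writing.
#' @param adapter,min_overlap,error_rate see \code{\link{trim_adapter}}.
#' @param n_random_bases see \code{\link{strip_random_bases}}.
#' @param min_len,max_len see \code{\link{length_gate}}.
#' @param trim whether to perform adapter search at all; with
#'   \code{trim = FALSE} reads are taken as already adapter-free and only
#'   length-gated (no random-base stripping), which makes preprocessing of
#'   an already-processed file a no-op.
#' @return A list of class \code{preprocess_stats}: \code{input_reads},
#'   \code{adapter_found}, \code{passed_length}, \code{discarded_no_adapter},
#'   \code{discarded_length}, plus \code{out_path}. Counts partition the
#'   input: \code{input = passed + no_adapter + length}.
#' @export
preprocess_fastq <- function(in_path, out_path = NULL,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_overlap = 6L, error_rate = 0.1,
                             n_random_bases = 4L,
                             min_len = 16L, max_len = 28L, trim = TRUE) {
  parsed <- tryCatch({
    # muffle the reader's cosmetic metadata-column note
    fq <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(in_path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(ids = names(fq), reads = as.character(fq),
         quals = as.character(Biostrings::quality(fq)))
  }, error = function(e)
    stop(sprintf("malformed FASTQ in '%s': %s", in_path, conditionMessage(e)),
         call. = FALSE))
  reads <- parsed$reads
  quals <- parsed$quals
  bad <- which(nchar(quals) != nchar(reads))
  if (length(bad) > 0)
    stop(sprintf("malformed FASTQ in '%s': quality length mismatch at record %d",
                 in_path, bad[1]), call. = FALSE)
  n <- length(reads)

  if (trim) {
    pos <- adapter_position(reads, adapter, min_overlap, error_rate)
    found <- !is.na(pos)
    ins_start <- rep(n_random_bases + 1L, n)
    ins_end <- ifelse(found, pos - 1L - n_random_bases, 0L)
  } else {
    found <- rep(TRUE, n)
    ins_start <- rep(1L, n)
    ins_end <- nchar(reads)
  }
  ins_len <- pmax(ins_end - ins_start + 1L, 0L)
  pass <- found & ins_len >= min_len & ins_len <= max_len

  stats <- list(input_reads = n,
                adapter_found = sum(found),
                passed_length = sum(pass),
                discarded_no_adapter = sum(!found),
                discarded_length = sum(found & !pass),
                out_path = out_path)
  class(stats) <- "preprocess_stats"

  if (!is.null(out_path)) {
    keep <- which(pass)
    seqs <- substr(reads[keep], ins_start[keep], ins_end[keep])
    qs <- substr(quals[keep], ins_start[keep], ins_end[keep])
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- parsed$ids[keep]
    # suppress the cosmetic metadata-column note emitted by the writer
    suppressWarnings(
      Biostrings::writeXStringSet(x, out_path, format = "fastq",
                                  qualities = Biostrings::BStringSet(qs),
                                  compress = grepl("\\.gz$", out_path)))
  }
  stats
}

#' @export
print.preprocess_stats <- function(x, ...) {
  cat(sprintf(paste0("preprocess_stats: %d reads in, %d with adapter, ",
                     "%d passed (no adapter: %d, length: %d)\n"),
              x$input_reads, x$adapter_found, x$passed_length,
              x$discarded_no_adapter, x$discarded_length))
  invisible(x)
}

#' @rdname preprocess_fastq
#' @param x a \code{preprocess_stats} object.
#' @export
as.data.frame.preprocess_stats <- function(x, ...) {
  data.frame(input_reads = x$input_reads, adapter_found = x$adapter_found,
             passed_length = x$passed_length,
             discarded_no_adapter = x$discarded_no_adapter,
             discarded_length = x$discarded_length)
}
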