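#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed derived from a master seed and a stream tag.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483587L)
}

# Random DNA strings of the given widths.
random_dna <- function(widths) {
  total <- sum(widths)
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  s <- paste(bases, collapse = "")
  substring(s, starts, ends)
}

# Resolve a miRNA name against a vector of row/assay names, tolerating the
# optional "hsa-" prefix on either side.
match_mirna <- function(names, target) {
  strip <- function(x) sub("^hsa-", "", x)
  i <- match(strip(target), strip(names))
  if (is.na(i)) return(NA_integer_)
  i
}

stop_missing_mirna <- function(names, target, context) {
  i <- match_mirna(names, target)
  if (is.na(i)) stop(sprintf("%s: miRNA '%s' not found", context, target), call. = FALSE)
  i
}

# Hamming distance between two equal-length DNA strings.
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}
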