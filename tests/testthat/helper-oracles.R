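# Independent oracles and fixture builders used across the suite.

# Build a mirna_reference by hand from mature sequences embedded in hairpins
# with the given flanks.
toy_reference <- function(matures, flank_up = NULL, flank_down = NULL) {
  n <- length(matures)
  if (is.null(flank_up)) flank_up <- replicate(n, paste(sample(c("A","C","G","T"), 10, TRUE), collapse = ""))
  if (is.null(flank_down)) flank_down <- replicate(n, paste(sample(c("A","C","G","T"), 10, TRUE), collapse = ""))
  flank_up <- rep_len(flank_up, n); flank_down <- rep_len(flank_down, n)
  ref <- list(
    mature = data.frame(name = names(matures), sequence = unname(matures),
                        hairpin_id = paste0("hp-", names(matures)),
                        start = nchar(flank_up),
                        end = nchar(flank_up) + nchar(matures),
                        stringsAsFactors = FALSE),
    hairpin = data.frame(id = paste0("hp-", names(matures)),
                         sequence = paste0(flank_up, matures, flank_down),
                         stringsAsFactors = FALSE)
  )
  class(ref) <- "mirna_reference"
  ref
}

# Exhaustive-enumeration alignment oracle, written independently of the
# package's dictionary-based implementation: try every mature and every 5'
# offset, count mismatches character-by-character only at positions falling
# inside the canonical mature interval, and pick the best candidate by
# (mismatches, |o5| + |o3|, name).
oracle_assign <- function(read, ref, max_shift = 3L, max_mismatch = 2L) {
  L <- nchar(read)
  rch <- strsplit(read, "")[[1]]
  best <- NULL
  for (k in order(ref$mature$name)) {
    s <- ref$mature$start[k]; e <- ref$mature$end[k]
    hp <- ref$hairpin$sequence[ref$hairpin$id == ref$mature$hairpin_id[k]]
    hch <- strsplit(hp, "")[[1]]
    for (o5 in -max_shift:max_shift) {
      o3 <- (s + o5 + L) - e
      if (abs(o3) > max_shift) next
      mm <- 0L
      for (i in seq_len(L)) {
        hpos <- s + o5 + i          # 1-based hairpin position
        inside <- hpos >= s + 1L && hpos <= e
        if (!inside) next           # extension bases are free here
        if (hpos < 1L || hpos > length(hch) || rch[i] != hch[hpos])
          mm <- mm + 1L
      }
      if (mm > max_mismatch) next
      cand <- list(mirna = ref$mature$name[k], o5 = o5, o3 = o3,
                   mismatches = mm, shift = abs(o5) + abs(o3))
      if (is.null(best) ||
          cand$mismatches < best$mismatches ||
          (cand$mismatches == best$mismatches && cand$shift < best$shift))
        best <- cand
    }
  }
  best
}

# Literal transcription of the published TMM definition: gene-wise M and A
# values against a reference sample (upper-quartile fraction closest to the
# mean), double trimming (30% on M, 5% on A), inverse-asymptotic-variance
# weights, factors normalized to multiply to 1.
oracle_tmm <- function(counts, trimM = 0.3, trimA = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- sapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    keep <- obs > 0 & rf > 0
    obs <- obs[keep]; rf <- rf[keep]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- 0.5 * log2((obs / nO) * (rf / nR))
    w <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k] / w[k]) / sum(1 / w[k]))
  })
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(counts))
}

# Literal transcription of the NormFinder variance decomposition used as the
# straight-from-formula oracle (k >= 3 assays).
oracle_normfinder <- function(cq, groups) {
  y <- -cq
  k <- nrow(y)
  gl <- unique(groups)
  m <- length(gl)
  d <- sweep(y, 2, colMeans(y))
  z <- sapply(gl, function(g) rowMeans(d[, groups == g, drop = FALSE]))
  s2 <- sapply(gl, function(g) apply(d[, groups == g, drop = FALSE], 1, stats::var))
  n_i <- sapply(gl, function(g) sum(groups == g))
  sig2 <- sapply(seq_along(gl), function(i)
    pmax((k / (k - 2)) * (s2[, i] - sum(s2[, i]) / (k * (k - 1))), 0))
  cgi <- z - rowMeans(z)
  samp_var <- sweep(sig2, 2, n_i, "/")
  gamma2 <- max(sum(cgi^2) / ((m - 1) * (k - 1)) - mean(samp_var), 0)
  shrunk <- if (gamma2 > 0) cgi * gamma2 / (gamma2 + samp_var) else cgi * 0
  rowMeans(abs(shrunk) + sqrt(samp_var))
}

random_read <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                   collapse = "")
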