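#' Configuration for a synthetic plasma miRNA cohort
#'
#' Defines the study conditions emulated by the generator: ten subjects each
#' sampled into four anticoagulant groups (ACD, Citrate, CTAD, EDTA), a
#' plasma miRNA repertoire of ~350 species with a heavy-tailed abundance
#' distribution (miR-451a and miR-486-5p dominating), per-sample hemolysis
#' fractions whose group means are strictly largest in EDTA, an RBC-panel
#' abundance spike proportional to hemolysis, isomiR sequence variation
#' around canonical sequences, absorbances increasing with hemolysis, Cq
#' values log-linearly related to abundance, and occasional degenerate
#' samples with a low miRNA read fraction.
#'
#' @param n_subjects number of subjects; each contributes one sample per group.
#' @param groups ordered character vector of anticoagulant group labels.
#' @param n_mirnas size of the miRNA repertoire.
#' @param hemolysis_mean named numeric: mean hemolysis fraction per group;
#'   the EDTA-like group (last label by default) must be strictly largest
#'   (an all-equal vector, e.g. all zero, is allowed for null experiments).
#' @param rbc_spike coefficient mapping hemolysis fraction to the abundance
#'   multiplier of RBC-panel miRNAs (\code{1 + rbc_spike * h});
#'   hemolysis-susceptible miRNAs receive half this coefficient.
#' @param library_depth_mean mean total reads per sample.
#' @param dropout_rate probability that a sample is degenerate (low miRNA
#'   fraction, high unaligned fraction).
#' @param isomir_rates list of per-read modification probabilities:
#'   \code{trim3}, \code{ext3}, \code{ext3_templated_frac}, \code{offset5},
#'   \code{snv}.
#' @param subject_sd log-scale SD of subject-specific baseline deviations.
#' @param cq_intercept,cq_sd log-linear Cq model: \code{Cq = intercept -
#'   log2(abundance proportion) + N(0, cq_sd)}.
#' @param panels origin panels (see \code{\link{default_origin_panels}}).
#' @param adapter 3' adapter sequence appended to simulated reads.
#' @param seed master seed driving all substreams.
#' @return A validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 10L,
                          groups = c("ACD", "Citrate", "CTAD", "EDTA"),
                          n_mirnas = 350L,
                          hemolysis_mean = c(ACD = 0.030, Citrate = 0.030,
                                             CTAD = 0.025, EDTA = 0.150),
                          rbc_spike = 30,
                          library_depth_mean = 1e5,
                          dropout_rate = 0.05,
                          isomir_rates = list(trim3 = 0.30, ext3 = 0.15,
                                              ext3_templated_frac = 0.7,
                                              offset5 = 0.10, snv = 0.05),
                          subject_sd = 0.15,
                          cq_intercept = 13.2, cq_sd = 0.15,
                          panels = default_origin_panels(),
                          adapter = "TGGAATTCTCGGGTGCCAAGG",
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), groups = as.character(groups),
              n_mirnas = as.integer(n_mirnas), hemolysis_mean = hemolysis_mean,
              rbc_spike = rbc_spike, library_depth_mean = library_depth_mean,
              dropout_rate = dropout_rate, isomir_rates = isomir_rates,
              subject_sd = subject_sd, cq_intercept = cq_intercept,
              cq_sd = cq_sd, panels = panels, adapter = adapter,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (length(cfg$groups) < 1) stop("group list must be non-empty")
  if (cfg$n_subjects < 1) stop("n_subjects must be positive")
  if (cfg$n_mirnas < 1) stop("n_mirnas must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop("dropout_rate must be a probability in [0, 1]")
  for (r in c("trim3", "ext3", "ext3_templated_frac", "offset5", "snv")) {
    v <- cfg$isomir_rates[[r]]
    if (is.null(v) || v < 0 || v > 1)
      stop(sprintf("isomir rate '%s' must be a probability in [0, 1]", r))
  }
  if (is.null(names(cfg$hemolysis_mean)) ||
      !setequal(names(cfg$hemolysis_mean), cfg$groups))
    stop("hemolysis_mean must be named by group")
  if (any(cfg$hemolysis_mean < 0)) stop("hemolysis means must be nonnegative")
  hm <- cfg$hemolysis_mean[cfg$groups]
  edta <- grep("EDTA", cfg$groups, value = TRUE)
  # EDTA must dominate strictly, except in the all-equal (e.g. hemolysis-free
  # null) configuration used for calibration experiments
  if (length(edta) == 1 && stats::var(hm) > 0) {
    if (!all(hm[edta] > hm[setdiff(cfg$groups, edta)]))
      stop("the EDTA group's hemolysis mean must be strictly largest")
  }
  if (cfg$rbc_spike < 0) stop("rbc_spike must be >= 0")
  invisible(cfg)
}

# Population relative abundance weights: log-normal body with a forced
# heavy tail so that miR-451a + miR-486-5p dominate (~35-40% of reads at
# baseline), other panel members sit in the high-moderate range, and the
# normalization control miR-30e-5p is lowly but reliably expressed.
population_weights <- function(ref, panels) {
  n <- nrow(ref$mature)
  w <- exp(stats::rnorm(n, 0, 1.5))
  names(w) <- ref$mature$name
  w <- w / sum(w)
  boost <- function(name, target) {
    i <- match_mirna(names(w), name)
    if (!is.na(i)) w[i] <<- target
  }
  # targets are fractions of total weight before renormalization
  boost("miR-451a", 0.22)
  boost("miR-486-5p", 0.16)
  for (m in setdiff(panels$rbc, c("miR-451a", "miR-486-5p")))
    boost(m, stats::runif(1, 0.008, 0.02))
  for (m in setdiff(panels$platelet, panels$rbc))
    boost(m, stats::runif(1, 0.008, 0.02))
  for (m in panels$hemolysis_susceptible)
    boost(m, stats::runif(1, 0.002, 0.006))
  # low but reliably counted at the default depth (normalization control)
  boost("miR-30e-5p", 1.5e-3)
  w / sum(w)
}

#' Generate a synthetic plasma cohort with known ground truth
#'
#' Draws a full cohort under the configured study conditions: per-subject
#' baseline abundance profiles; per-sample hemolysis fractions (gamma
#' distributed around the group mean); RBC-panel abundances multiplied by
#' \code{1 + rbc_spike * h} (hemolysis-susceptible members by
#' \code{1 + rbc_spike/2 * h}) and renormalized; miRNA read counts drawn
#' multinomially at the sample's miRNA depth; absorbances A414/A385 rising
#' linearly with hemolysis; Cq values log-linear in abundance with Gaussian
#' noise (degenerate samples shifted up, emulating diluted miRNA input); and
#' degenerate samples flagged with a low miRNA read percentage and a high
#' unaligned fraction.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param reference optionally a pre-built \code{mirna_reference}; by default
#'   generated from the config's seed.
#' @param fastq_dir if non-NULL, simulated reads are written as one FASTQ
#'   file per sample into this directory (see \code{\link{simulate_reads}}).
#' @return An object of class \code{plasmir_cohort}: list with
#'   \code{config}, \code{reference}, \code{counts} (miRNA x sample integer
#'   matrix), \code{metadata} (sample_id, subject_id, group,
#'   percent_mirna_reads, unaligned_fraction, degenerate), \code{absorbance}
#'   (sample_id, A385, A414), \code{cq} (assay x sample matrix),
#'   \code{truth} (hemolysis fractions, source proportions, baselines,
#'   panel membership, degenerate flags), and \code{fastq} (paths or NULL).
#' @export
generate_cohort <- function(config = cohort_config(), reference = NULL,
                            fastq_dir = NULL) {
  validate_cohort_config(config)
  if (config$library_depth_mean <= 0) stop("library depth must be positive")
  if (is.null(reference))
    reference <- generate_reference(config$n_mirnas, seed = config$seed)
  panels <- resolve_panels(config$panels, reference$mature$name)
  if (length(panels$rbc) == 0 || length(panels$platelet) == 0)
    stop("configuration error: origin-panel members absent from the reference")
  missing_panel <- setdiff(unlist(config$panels[c("rbc", "platelet")]),
                           reference$mature$name)
  if (length(missing_panel) > 0 && nrow(reference$mature) >= length(sentinel_mirnas()))
    stop(sprintf("panel members absent from reference: %s",
                 paste(missing_panel, collapse = ", ")))

  with_seed(derive_seed(config$seed, "cohort"), {
    groups <- config$groups
    subjects <- sprintf("s%02d", seq_len(config$n_subjects))
    meta <- expand.grid(subject_id = subjects, group = groups,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$sample_id <- paste0(meta$subject_id, "_", meta$group)
    n_samp <- nrow(meta)
    mirnas <- reference$mature$name

    w_pop <- population_weights(reference, panels)
    base <- sapply(subjects, function(s) {
      b <- w_pop * exp(stats::rnorm(length(w_pop), 0, config$subject_sd))
      b / sum(b)
    })
    rownames(base) <- mirnas

    hm <- config$hemolysis_mean[meta$group]
    h <- stats::rgamma(n_samp, shape = 2, scale = pmax(hm, 1e-12) / 2)
    h[hm == 0] <- 0

    spike <- rep(1, length(mirnas))
    i_rbc <- match(panels$rbc, mirnas)
    i_hs <- match(panels$hemolysis_susceptible, mirnas)
    abund <- matrix(0, length(mirnas), n_samp,
                    dimnames = list(mirnas, meta$sample_id))
    for (j in seq_len(n_samp)) {
      a <- base[, meta$subject_id[j]]
      a[i_rbc] <- a[i_rbc] * (1 + config$rbc_spike * h[j])
      a[i_hs] <- a[i_hs] * (1 + 0.5 * config$rbc_spike * h[j])
      abund[, j] <- a / sum(a)
    }

    degenerate <- stats::runif(n_samp) < config$dropout_rate
    pct_mirna <- ifelse(degenerate,
                        stats::runif(n_samp, 5, 12),
                        100 * stats::rbeta(n_samp, 30, 10))
    unaligned <- ifelse(degenerate,
                        stats::runif(n_samp, 55, 75),
                        stats::runif(n_samp, 3, 15))

    depth_total <- stats::rpois(n_samp, config$library_depth_mean)
    depth_mirna <- pmax(round(depth_total * pct_mirna / 100), 1L)
    counts <- matrix(0L, length(mirnas), n_samp,
                     dimnames = list(mirnas, meta$sample_id))
    for (j in seq_len(n_samp))
      counts[, j] <- stats::rmultinom(1, depth_mirna[j], abund[, j])[, 1]

    # absorbance model: free hemoglobin peaks at 414 nm, weaker rise at 385 nm
    a414 <- 0.05 + 2.5 * h + stats::rnorm(n_samp, 0, 0.005)
    a385 <- 0.04 + 0.7 * h + stats::rnorm(n_samp, 0, 0.005)
    absorbance <- data.frame(sample_id = meta$sample_id,
                             A385 = a385, A414 = a414)

    assay <- qpcr_assay_panel()
    i_assay <- vapply(assay$name, function(nm) match_mirna(mirnas, nm), 0L)
    cq <- matrix(NA_real_, nrow(assay), n_samp,
                 dimnames = list(assay$name, meta$sample_id))
    ok <- !is.na(i_assay)
    for (j in seq_len(n_samp)) {
      p <- abund[i_assay[ok], j]
      shift <- if (degenerate[j]) 6 else 0
      cq[ok, j] <- config$cq_intercept - log2(pmax(p, 1e-12)) + shift +
        stats::rnorm(sum(ok), 0, config$cq_sd)
    }
    cq <- pmin(pmax(cq, 1), 45)

    src <- cbind(
      rbc = colSums(abund[i_rbc, , drop = FALSE]),
      platelet = colSums(abund[match(panels$platelet, mirnas), , drop = FALSE])
    )
    src <- cbind(src, other = 1 - rowSums(src))
    rownames(src) <- meta$sample_id

    meta <- meta[, c("sample_id", "subject_id", "group")]
    meta$percent_mirna_reads <- pct_mirna
    meta$unaligned_fraction <- unaligned
    meta$degenerate <- degenerate

    truth <- list(hemolysis_fraction = stats::setNames(h, meta$sample_id),
                  source_proportions = src,
                  baseline = base,
                  abundance = abund,
                  panels = panels,
                  degenerate = stats::setNames(degenerate, meta$sample_id))

    fastq <- NULL
    if (!is.null(fastq_dir)) {
      dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
      fastq <- character(n_samp)
      for (j in seq_len(n_samp)) {
        sim <- simulate_reads(reference, abund[, j],
                              n_reads = depth_total[j],
                              frac_mirna = pct_mirna[j] / 100,
                              isomir_rates = config$isomir_rates,
                              adapter = config$adapter,
                              seed = derive_seed(config$seed,
                                                 paste0("reads_", meta$sample_id[j])))
        fastq[j] <- file.path(fastq_dir, paste0(meta$sample_id[j], ".fastq"))
        write_fastq(sim$reads, fastq[j],
                    id_prefix = paste0(meta$sample_id[j], "_r"))
      }
      names(fastq) <- meta$sample_id
    }

    out <- list(config = config, reference = reference, counts = counts,
                metadata = meta, absorbance = absorbance, cq = cq,
                truth = truth, fastq = fastq)
    class(out) <- "plasmir_cohort"
    out
  })
}

#' @export
print.plasmir_cohort <- function(x, ...) {
  cat(sprintf("plasmir_cohort: %d miRNAs x %d samples (%d subjects, groups: %s)\n",
              nrow(x$counts), ncol(x$counts), x$config$n_subjects,
              paste(x$config$groups, collapse = ", ")))
  invisible(x)
}

#' Simulate raw small-RNA reads for one sample
#'
#' Draws reads from a miRNA abundance vector with isomiR variation (3'
#' trimming, templated and non-templated 3' extension, 5' offsets, internal
#' single-nucleotide variants), wraps each insert with 4 randomized bases on
#' both ends plus the 3' adapter, and dilutes with uniform-random non-miRNA
#' inserts to reach the requested miRNA fraction. Variants whose insert
#' length would leave the 16-28 nt window are emitted canonical, so that
#' every miRNA-derived read survives the length gate.
#'
#' @param reference a \code{mirna_reference}.
#' @param abundance nonnegative abundance vector named by mature miRNA.
#' @param n_reads total reads to emit (> 0).
#' @param frac_mirna fraction of reads drawn from miRNAs (rest are random).
#' @param isomir_rates see \code{\link{cohort_config}}.
#' @param adapter 3' adapter appended to every read.
#' @param n_random_bases randomized bases on each end of the insert.
#' @param seed integer seed.
#' @return list with \code{reads} (character), \code{truth_counts}
#'   (named integer vector of true per-miRNA read counts),
#'   \code{truth_isomir} (per-miRNA-read data.frame of the planted isoform:
#'   mirna, insert, offset5, offset3, templated flags, snv) and
#'   \code{n_random} (number of non-miRNA reads).
#' @export
simulate_reads <- function(reference, abundance, n_reads,
                           frac_mirna = 0.75,
                           isomir_rates = list(trim3 = 0.30, ext3 = 0.15,
                                               ext3_templated_frac = 0.7,
                                               offset5 = 0.10, snv = 0.05),
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           n_random_bases = 4L, seed = 1L) {
  if (n_reads <= 0) stop("cannot emit an empty FASTQ: n_reads must be > 0")
  stopifnot(length(abundance) == nrow(reference$mature))
  with_seed(seed, {
    n_mi <- round(n_reads * frac_mirna)
    n_rand <- n_reads - n_mi
    p <- abundance / sum(abundance)
    m <- sample.int(length(p), n_mi, replace = TRUE, prob = p)

    mat <- reference$mature
    hp_seq <- reference$hairpin$sequence[match(mat$hairpin_id,
                                               reference$hairpin$id)]
    len <- mat$end - mat$start

    r <- isomir_rates
    # 3' end: trim with prob trim3, extend with prob ext3, else canonical end
    u3 <- stats::runif(n_mi)
    o3 <- integer(n_mi)
    o3[u3 < r$trim3] <- -sample(1:3, sum(u3 < r$trim3), replace = TRUE,
                                prob = c(0.6, 0.3, 0.1))
    ext3 <- u3 >= r$trim3 & u3 < r$trim3 + r$ext3
    o3[ext3] <- sample(1:2, sum(ext3), replace = TRUE, prob = c(0.8, 0.2))
    ext3_templ <- ext3 & stats::runif(n_mi) < r$ext3_templated_frac
    # 5' end: small offsets either way
    u5 <- stats::runif(n_mi)
    o5 <- integer(n_mi)
    has5 <- u5 < r$offset5
    o5[has5] <- sample(c(-2L, -1L, 1L, 2L), sum(has5), replace = TRUE,
                       prob = c(0.1, 0.4, 0.4, 0.1))
    ext5_templ <- has5 & o5 < 0 & stats::runif(n_mi) < r$ext3_templated_frac
    snv <- stats::runif(n_mi) < r$snv

    L <- len[m] - o5 + o3
    bad <- L < 16L | L > 28L
    o5[bad] <- 0L; o3[bad] <- 0L

    # templated variant straight off the hairpin (1-based substr)
    ins <- substr(hp_seq[m], mat$start[m] + o5 + 1L, mat$end[m] + o3)

    alt_base <- function(b) {
      vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
    }
    # non-templated 3' extension: mutate the extension bases
    nt3 <- which(ext3 & !ext3_templ)
    for (i in nt3) {
      k <- o3[i]
      if (k <= 0) next
      n <- nchar(ins[i])
      tail_bases <- strsplit(substr(ins[i], n - k + 1L, n), "")[[1]]
      substr(ins[i], n - k + 1L, n) <- paste(alt_base(tail_bases), collapse = "")
    }
    # non-templated 5' extension
    nt5 <- which(has5 & o5 < 0 & !ext5_templ)
    for (i in nt5) {
      k <- -o5[i]
      head_bases <- strsplit(substr(ins[i], 1L, k), "")[[1]]
      substr(ins[i], 1L, k) <- paste(alt_base(head_bases), collapse = "")
    }
    # internal SNV at a position inside the mature-overlap region
    snv_done <- logical(n_mi)
    isnv <- which(snv)
    for (i in isnv) {
      n <- nchar(ins[i])
      lo <- max(1L, 1L - o5[i] + 1L)   # past any 5' extension
      hi <- n - max(0L, o3[i])         # before any 3' extension
      if (hi <= lo) next
      pos <- sample(lo:hi, 1L)
      substr(ins[i], pos, pos) <- alt_base(substr(ins[i], pos, pos))
      snv_done[i] <- TRUE
    }

    rand_ins <- if (n_rand > 0) random_dna(sample(18:24, n_rand, replace = TRUE))
                else character(0)
    inserts <- c(ins, rand_ins)
    nn <- length(inserts)
    wrap1 <- random_dna(rep(n_random_bases, nn))
    wrap2 <- random_dna(rep(n_random_bases, nn))
    reads <- paste0(wrap1, inserts, wrap2, adapter)

    truth <- tabulate(m, nbins = length(p))
    names(truth) <- mat$name
    truth_isomir <- data.frame(
      mirna = mat$name[m], insert = ins, offset5 = o5, offset3 = o3,
      ext3_templated = ifelse(o3 > 0, ext3_templ, NA),
      ext5_templated = ifelse(o5 < 0, ext5_templ, NA),
      snv = snv_done, stringsAsFactors = FALSE)
    list(reads = reads, truth_counts = truth, truth_isomir = truth_isomir,
         n_random = n_rand)
  })
}

#' Write reads to a FASTQ file
#'
#' @param reads character vector of read sequences.
#' @param path output path (\code{.gz} suffix triggers gzip compression).
#' @param id_prefix read identifier prefix.
#' @param qualities optional character vector of per-read quality strings;
#'   defaults to constant Q40.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path, id_prefix = "read", qualities = NULL) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0(id_prefix, seq_along(reads))
  if (is.null(qualities)) qualities <- strrep("I", nchar(reads))
  q <- Biostrings::BStringSet(qualities)
  suppressWarnings(
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path)))
  invisible(path)
}
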