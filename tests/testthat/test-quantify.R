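test_that("a read equal to a mature sequence maps to it exactly", {
  ref <- generate_reference(20, seed = 51)
  m <- ref$mature[3, ]
  a <- assign_read(m$sequence, ref)
  expect_equal(a$mirna, m$name)
  expect_equal(a$offset5, 0L)
  expect_equal(a$offset3, 0L)
  expect_equal(a$mismatches, 0L)
})

test_that("reads matching nothing within bounds are unaligned", {
  ref <- generate_reference(5, seed = 52)
  set.seed(52)
  a <- assign_read(random_read(24), ref)
  expect_true(is.na(a$mirna))
  expect_error(assign_reads("ACGTXT", ref), "ACGTN")
})

test_that("equidistant reads resolve to the lexicographically smaller name", {
  seqv <- "ACGTTGCAGGACCTATGCAAGT"
  ref <- toy_reference(c(zeta = seqv, alpha = seqv))
  a <- assign_read(seqv, ref)
  expect_equal(a$mirna, "alpha")
  # also for a shared trimmed variant
  a2 <- assign_read(substr(seqv, 1, 21), ref)
  expect_equal(a2$mirna, "alpha")
  expect_equal(a2$offset3, -1L)
})

test_that("assignment agrees with exhaustive placement enumeration", {
  set.seed(53)
  for (rep in 1:4) {
    ref <- toy_reference(stats::setNames(
      vapply(1:5, function(i) random_read(sample(18:25, 1)), ""),
      paste0("m", sample(5))))
    reads <- character(0)
    for (i in 1:60) {
      k <- sample(5, 1)
      m <- ref$mature$sequence[k]
      r <- m
      # random perturbation: trim/extend ends, mutate bases
      if (runif(1) < 0.5) r <- substr(r, sample(0:3, 1) + 1, nchar(r))
      if (runif(1) < 0.5) r <- substr(r, 1, nchar(r) - sample(0:3, 1))
      if (runif(1) < 0.4) r <- paste0(r, random_read(sample(1:3, 1)))
      if (runif(1) < 0.3) r <- paste0(random_read(sample(1:2, 1)), r)
      if (runif(1) < 0.5 && nchar(r) > 4) {
        p <- sample(nchar(r), 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      reads <- c(reads, r)
    }
    reads <- c(reads, replicate(15, random_read(sample(16:28, 1))))
    got <- assign_reads(reads, ref)
    for (i in seq_along(reads)) {
      exp <- oracle_assign(reads[i], ref)
      if (is.null(exp)) {
        expect_true(is.na(got$mirna[i]), info = reads[i])
      } else {
        expect_equal(got$mirna[i], exp$mirna, info = reads[i])
        expect_equal(got$offset5[i], exp$o5, info = reads[i])
        expect_equal(got$offset3[i], exp$o3, info = reads[i])
        expect_equal(got$mismatches[i], exp$mismatches, info = reads[i])
      }
    }
  }
})

test_that("isomiR classes follow the taxonomy definitions on a crafted hairpin", {
  # hairpin: flank ends with G | mature | next bases are CA
  mature <- "TAGCTAGCTAGCTAGCTAGC"
  ref <- toy_reference(c(mirX = mature),
                       flank_up = "AAAAAAAAAG", flank_down = "CATTTTTTTT")
  cls <- function(read) {
    a <- assign_read(read, ref)
    classify_isomir(a, ref)
  }
  expect_equal(cls(mature)$class_labels, "canonical")
  t3 <- cls(substr(mature, 1, 19))
  expect_equal(t3$class_labels, "trim3")
  expect_equal(t3$offset3, -1L)
  e3t <- cls(paste0(mature, "C"))          # next hairpin base is C
  expect_equal(e3t$class_labels, "ext3_templated")
  e3n <- cls(paste0(mature, "G"))          # differs from hairpin C
  expect_equal(e3n$class_labels, "ext3_nontemplated")
  e5t <- cls(paste0("G", mature))          # upstream hairpin base is G
  expect_equal(e5t$class_labels, "ext5_templated")
  e5n <- cls(paste0("T", mature))
  expect_equal(e5n$class_labels, "ext5_nontemplated")
  t5 <- cls(substr(mature, 2, 20))
  expect_equal(t5$class_labels, "trim5")
  expect_equal(t5$offset5, 1L)
  poly <- mature
  substr(poly, 7, 7) <- "A"                # G -> A internal substitution
  pa <- cls(poly)
  expect_equal(pa$class_labels, "polymorphic")
  expect_equal(pa$internal_mismatches$position, 7L)
  expect_equal(pa$internal_mismatches$read_base, "A")
  # every aligned read gets at least one label; canonical is exclusive
  for (r in list(mature, substr(mature, 1, 19), paste0(mature, "C"))) {
    labs <- cls(r)$class_labels
    expect_gte(length(labs), 1)
    if ("canonical" %in% labs) expect_equal(labs, "canonical")
  }
})

test_that("classifier recovers the generator's planted isoform structure", {
  ref <- generate_reference(30, seed = 61)
  ab <- stats::setNames(rep(1, 30), ref$mature$name)
  sim <- simulate_reads(ref, ab, n_reads = 4000, frac_mirna = 1, seed = 62)
  asn <- assign_reads(sim$truth_isomir$insert, ref)
  agree <- mean(asn$mirna == sim$truth_isomir$mirna &
                  asn$offset5 == sim$truth_isomir$offset5 &
                  asn$offset3 == sim$truth_isomir$offset3, na.rm = TRUE)
  expect_gt(agree, 0.95)
  # aggregated class fractions close to the planted rates
  ok <- which(asn$mirna == sim$truth_isomir$mirna)
  labs <- lapply(ok, function(i)
    classify_isomir(asn[i, ], ref)$class_labels)
  frac <- function(lbl) mean(vapply(labs, function(l) lbl %in% l, TRUE))
  planted_trim3 <- mean(sim$truth_isomir$offset3[ok] < 0)
  expect_lt(abs(frac("trim3") - planted_trim3), 0.02)
  expect_lt(abs(frac("trim3") - 0.30), 0.06)  # configured rate minus clamping
  ext3 <- frac("ext3_templated") + frac("ext3_nontemplated")
  expect_lt(abs(ext3 - 0.15), 0.05)
  expect_gt(frac("ext3_templated"), frac("ext3_nontemplated"))
  expect_lt(abs(frac("polymorphic") - 0.05), 0.03)
})

test_that("count aggregation pools isoforms and conserves totals", {
  mature <- "ACGGATTCAGCATGCAAGTCC"
  ref <- toy_reference(c(mirA = mature))
  reads <- c(mature, mature, substr(mature, 1, 20))  # canonical x2 + trim
  asn <- assign_reads(reads, ref)
  cs <- count_samples(list(s1 = asn), ref)
  expect_equal(unname(cs$counts["mirA", "s1"]), 3L)
  expect_equal(nrow(cs$isomirs), 2)          # two distinct sequences
  expect_equal(sum(cs$isomirs$s1), 3)
  expect_error(count_samples(stats::setNames(list(asn, asn), c("a", "a")), ref),
               "uniquely named")
})

test_that("column sums equal per-sample assigned totals within multinomial error", {
  ref <- generate_reference(25, seed = 63)
  set.seed(63)
  ab <- rexp(25); names(ab) <- ref$mature$name
  sim <- simulate_reads(ref, ab, n_reads = 5000, frac_mirna = 0.9, seed = 64)
  # inserts of miRNA reads plus unalignable random inserts
  rnd <- replicate(500, random_read(sample(18:24, 1)))
  asn <- assign_reads(c(sim$truth_isomir$insert, rnd), ref)
  cs <- count_samples(list(s1 = asn), ref)
  expect_equal(sum(cs$counts[, "s1"]), sum(!is.na(asn$mirna)))
  # chi-square goodness of fit of counts against true proportions
  p <- ab / sum(ab)
  obs <- cs$counts[, "s1"]
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("the noisy-read filter implements the stated conjunction", {
  m <- matrix(0, 3, 20, dimnames = list(c("a", "b", "c"), paste0("s", 1:20)))
  m["a", 1] <- 40          # mean 2.0, 95% zeros -> removed
  m["b", 1:10] <- 4        # mean 2.0, 50% zeros -> retained
  m["c", ] <- 5            # clearly expressed
  f <- filter_noisy(m)
  expect_setequal(rownames(f), c("b", "c"))

  set.seed(65)
  r <- matrix(rpois(50 * 20, 0.8), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  f2 <- filter_noisy(r)
  keep_oracle <- vapply(seq_len(nrow(r)), function(i)
    !(mean(r[i, ]) <= 2 && mean(r[i, ] == 0) >= 0.9), TRUE)
  expect_identical(rownames(f2), rownames(r)[keep_oracle])
})

test_that("CPM normalizes columns to one million and is scale invariant", {
  m <- matrix(c(5, 999995, 10, 999990), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cp <- cpm_matrix(m)
  expect_equal(unname(cp["a", "s1"]), 5)
  expect_equal(unname(colSums(cp)), c(1e6, 1e6))
  expect_equal(cpm_matrix(m * 2), cp)
  m0 <- cbind(m, s3 = c(0, 0))
  expect_error(cpm_matrix(m0), "s3")
})

test_that("the expression filter is strict at the CPM boundary", {
  cp <- matrix(2, 1, 12, dimnames = list("a", paste0("s", 1:12)))
  expect_length(expression_filter(cp), 0)          # 2.0 is not > 2
  cp2 <- rbind(a = c(rep(2.1, 10), 0, 0))
  colnames(cp2) <- paste0("s", 1:12)
  expect_equal(expression_filter(cp2), "a")        # exactly 10 samples

  set.seed(66)
  r <- matrix(runif(40 * 15, 0, 5), 40, 15,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:15)))
  keep <- expression_filter(r, 2, 10)
  oracle <- rownames(r)[vapply(seq_len(nrow(r)), function(i)
    sum(r[i, ] > 2) >= 10, TRUE)]
  expect_identical(keep, oracle)
})

test_that("the isoform filter gates on parent expression and isoform depth", {
  cp <- matrix(50, 2, 12, dimnames = list(c("pA", "pB"), paste0("s", 1:12)))
  iso <- data.frame(mirna = c("pA", "pA", "pB"),
                    sequence = c("AAA", "AAC", "CCC"),
                    stringsAsFactors = FALSE)
  for (s in paste0("s", 1:12)) iso[[s]] <- c(10, 100, 12)
  out <- isoform_filter(iso, cp)
  # mean exactly 10 is removed (strict)
  expect_false("AAA" %in% out$retained$sequence)
  expect_setequal(out$retained$sequence, c("AAC", "CCC"))
  # an isoform carrying 100% of a retained parent appears as major
  expect_true("CCC" %in% out$major$sequence)
  expect_error(isoform_filter(
    data.frame(mirna = "zz", sequence = "AA", s1 = 5), cp), "absent")

  set.seed(67)
  iso2 <- data.frame(mirna = sample(c("pA", "pB"), 30, TRUE),
                     sequence = paste0("seq", 1:30), stringsAsFactors = FALSE)
  for (s in paste0("s", 1:12)) iso2[[s]] <- rpois(30, 11)
  got <- isoform_filter(iso2, cp)$retained$sequence
  cnt <- as.matrix(iso2[, paste0("s", 1:12)])
  oracle <- iso2$sequence[rowMeans(cnt) > 10]    # both parents pass here
  expect_identical(got, oracle)
})

test_that("sample QC gates follow the strict 15 percent rule", {
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     percent_mirna_reads = c(15, 14.9, 80, 80),
                     unaligned_fraction = c(10, 10, 60, 50))
  qc <- sample_qc_gate(meta)
  expect_true("a" %in% qc$retained)               # exactly 15 retained
  expect_false("b" %in% qc$retained)
  expect_equal(qc$exclusions$reason[qc$exclusions$sample_id == "b"],
               "low_mirna_fraction")
  # unaligned > 50 flagged but retained unless strict
  expect_true("c" %in% qc$retained)
  expect_equal(qc$exclusions$reason[qc$exclusions$sample_id == "c"],
               "high_unaligned")
  expect_false("c" %in% sample_qc_gate(meta, strict = TRUE)$retained)
  expect_true("d" %in% sample_qc_gate(meta, strict = TRUE)$retained)
})

test_that("planted degenerate cohort samples are exactly the exclusions", {
  co <- generate_cohort(cohort_config(seed = 17, dropout_rate = 0.2))
  qc <- sample_qc_gate(co$metadata, strict = TRUE)
  planted <- co$metadata$sample_id[co$metadata$degenerate]
  expect_setequal(setdiff(co$metadata$sample_id, qc$retained), planted)
})

test_that("noise and expression filters are stable under row permutation", {
  set.seed(68)
  m <- matrix(rpois(60 * 15, 3), 60, 15,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:15)))
  perm <- sample(nrow(m))
  a <- expression_filter(cpm_matrix(filter_noisy(m)))
  b <- expression_filter(cpm_matrix(filter_noisy(m[perm, ])))
  expect_setequal(a, b)
})
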