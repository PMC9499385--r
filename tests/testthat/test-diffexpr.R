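test_that("TMM factors are unity for identical or globally rescaled libraries", {
  set.seed(91)
  base <- rpois(50, 100) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(m) <- paste0("g", 1:50)
  expect_equal(unname(tmm_factors(m)), rep(1, 3), tolerance = 1e-9)
  m2 <- cbind(s1 = base, s2 = 2 * base)
  rownames(m2) <- paste0("g", 1:50)
  expect_equal(unname(tmm_factors(m2)), rep(1, 2), tolerance = 1e-9)
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2 samples")
  expect_error(tmm_factors(cbind(m, s4 = 0)), "s4")
})

test_that("TMM matches a literal transcription of the published formula", {
  set.seed(92)
  for (i in 1:5) {
    cm <- matrix(rnbinom(20 * 4, mu = 500, size = 5), 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    cm["g1", "s2"] <- cm["g1", "s2"] * 8   # one dominant gene doubles+ in s2
    f <- tmm_factors(cm)
    expect_equal(f, oracle_tmm(cm), tolerance = 1e-8)
    # the distorted sample is down-weighted relative to unity
    expect_lt(f[["s2"]], 1)
    expect_equal(prod(f), 1, tolerance = 1e-9)
  }
})

test_that("TMM factors are invariant to sample order", {
  set.seed(93)
  cm <- matrix(rnbinom(40 * 5, mu = 200, size = 3), 40,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  f <- tmm_factors(cm)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(tmm_factors(cm[, perm])[colnames(cm)], f, tolerance = 1e-12)
})

test_that("pairwise contrasts are antisymmetric and complete", {
  set.seed(94)
  n_g <- 80
  subj <- rep(paste0("s", 1:6), 4)
  grp <- rep(c("ACD", "Citrate", "CTAD", "EDTA"), each = 6)
  mu <- outer(exp(rnorm(n_g, log(100), 1)), exp(rnorm(24, 0, 0.2)))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), n_g,
                   dimnames = list(paste0("g", 1:n_g), paste0("x", 1:24)))
  de <- fit_pairwise_de(counts, grp, subj)
  expect_equal(length(unique(de$contrast)), 6)   # all pairs of 4 groups
  expect_true(all(de$adj_p >= de$p_value))
  expect_true(all(de$significant == (de$adj_p < 0.05)))
  # flipping the factor order flips the contrast sign
  de2 <- fit_pairwise_de(counts, factor(grp, levels = rev(sort(unique(grp)))),
                         subj)
  a <- de[de$contrast == "Citrate_vs_ACD", ]
  b <- de2[de2$contrast == "ACD_vs_Citrate", ]
  expect_equal(a$log2fc[match(b$mirna, a$mirna)], -b$log2fc, tolerance = 1e-8)
})

test_that("pooled BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust_pooled(0.37), 0.37)
  expect_equal(bh_adjust_pooled(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-12)
  set.seed(95)
  p <- runif(200)
  adj <- bh_adjust_pooled(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust_pooled(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust_pooled(c(0.1, 1.2)), "0, 1")
})

test_that("the DE selection rule follows its three gates", {
  mk <- function(mirna, contrast, lfc, l2c, sig)
    data.frame(mirna = mirna, contrast = contrast, log2fc = lfc,
               mean_log2cpm = l2c, p_value = 0.01,
               adj_p = ifelse(sig, 0.01, 0.5), significant = sig)
  # expression gate: log2CPM 4.9 never passes
  r <- mk("a", "c1", 3, 4.9, TRUE)
  expect_length(attr(select_de(r), "de_mirnas"), 0)
  # one significant contrast with |lfc| > 1 passes at log2CPM 6
  r2 <- mk("b", "c1", 1.5, 6, TRUE)
  expect_equal(attr(select_de(r2), "de_mirnas"), "b")
  # three significant small-fold contrasts pass without the lfc branch
  r3 <- rbind(mk("c", "c1", 0.4, 6, TRUE), mk("c", "c2", 0.3, 6, TRUE),
              mk("c", "c3", 0.2, 6, TRUE))
  expect_equal(attr(select_de(r3), "de_mirnas"), "c")
  r4 <- r3[1:2, ]  # only two significant, small folds: fails
  expect_length(attr(select_de(r4), "de_mirnas"), 0)

  set.seed(96)
  rnd <- data.frame(
    mirna = rep(paste0("m", 1:30), each = 6),
    contrast = rep(paste0("c", 1:6), 30),
    log2fc = rnorm(180, 0, 1.2),
    mean_log2cpm = rep(runif(30, 2, 9), each = 6),
    p_value = runif(180), adj_p = runif(180))
  rnd$significant <- rnd$adj_p < 0.05
  got <- attr(select_de(rnd), "de_mirnas")
  oracle <- sort(unique(unlist(lapply(split(rnd, rnd$mirna), function(d) {
    if (mean(d$mean_log2cpm) > 5 && any(d$significant) &&
        (any(d$significant & abs(d$log2fc) > 1) || sum(d$significant) >= 3))
      d$mirna[1] else NULL
  }))))
  expect_equal(got, oracle)
})

test_that("null data with permuted labels keeps the type-I error nominal", {
  set.seed(97)
  n_g <- 300; n_subj <- 8
  subject <- rep(paste0("s", 1:n_subj), 2)
  group <- rep(c("A", "B"), each = n_subj)
  sub_eff <- exp(rnorm(n_subj, 0, 0.3))
  mu <- outer(exp(rnorm(n_g, log(200), 1)), sub_eff[rep(1:n_subj, 2)])
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), n_g,
                   dimnames = list(paste0("g", 1:n_g), paste0("x", 1:16)))
  de <- fit_pairwise_de(counts, group, subject)
  rate <- mean(de$p_value < 0.05)
  ci <- qbinom(c(0.0005, 0.9995), n_g, 0.05) / n_g
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
  expect_equal(sum(de$significant), 0)
})

test_that("subject blocking absorbs subject effects and preserves power", {
  # strong subject effect, no group effect: no DE calls when blocked
  set.seed(98)
  n_g <- 250
  subj <- rep(paste0("s", 1:8), 2)
  grp <- rep(c("A", "B"), each = 8)
  sub_eff <- matrix(rnorm(n_g * 8, 0, 1), n_g,
                    dimnames = list(NULL, unique(subj)))
  mu0 <- exp(rnorm(n_g, log(300), 1))
  mu <- sapply(seq_along(subj), function(j) mu0 * 2^sub_eff[, subj[j]])
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), n_g,
                   dimnames = list(paste0("g", 1:n_g), paste0("x", 1:16)))
  de0 <- select_de(fit_pairwise_de(counts, grp, subj))
  expect_equal(sum(de0$significant), 0)
  # with a true 2-fold effect on 50 genes, blocking recovers far more of
  # them than the unblocked analysis of the same data
  spiked <- paste0("g", 1:50)
  mu2 <- mu; mu2[1:50, grp == "B"] <- mu2[1:50, grp == "B"] * 2
  counts2 <- matrix(rnbinom(length(mu2), mu = mu2, size = 20), n_g,
                    dimnames = dimnames(counts))
  tp <- function(d) sum(d$significant & d$mirna %in% spiked)
  tpb <- tp(fit_pairwise_de(counts2, grp, subj, blocked = TRUE))
  tpu <- tp(fit_pairwise_de(counts2, grp, subj, blocked = FALSE))
  expect_gt(tpb, 40)
  expect_gt(tpb / max(tpu, 1), 1)
})

test_that("spiked cohorts recover RBC-panel miRNAs among DE calls", {
  co <- generate_cohort(cohort_config(seed = 37, library_depth_mean = 1e5))
  keep <- sample_qc_gate(co$metadata, strict = TRUE)$retained
  meta <- co$metadata[match(keep, co$metadata$sample_id), ]
  counts <- filter_noisy(co$counts[, keep])
  de <- select_de(fit_pairwise_de(counts, meta$group, meta$subject_id))
  demi <- attr(de, "de_mirnas")
  rbc <- co$truth$panels$rbc
  expect_gt(mean(rbc %in% demi), 0.8)
  # direction: elevated in EDTA for the recovered RBC panel members
  e <- de[de$mirna %in% intersect(rbc, demi) &
            de$contrast == "EDTA_vs_ACD", ]
  expect_true(all(e$log2fc > 0))
})
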