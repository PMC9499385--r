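#' Pipeline run configuration
#'
#' Bundles every stage parameter with its protocol default: the 3' adapter,
#' 4 randomized bases, the 16-28 nt insert window, the noisy-read filter
#' (mean <= 2 and zero in >= 90 percent of samples), the expression filter
#' (CPM > 2 in >= 10 samples), the sample QC gates (15 percent miRNA reads,
#' 50 percent unaligned, mean Cq 25), and the DE-selection thresholds
#' (mean log2CPM > 5, |log2FC| > 1 or >= 3 significant contrasts).
#'
#' @param cohort a \code{\link{cohort_config}} for the synthetic stage.
#' @param stages character vector of stage names to run, in fixed order.
#' @param use_reads simulate raw reads and run the preprocess + quantify
#'   stages on them (slower) instead of using the generator's count matrix.
#' @param min_cpm,min_samples expression-filter parameters.
#' @param min_mirna_pct,max_unaligned,strict_qc sample QC gate parameters.
#' @param max_mean_cq qPCR sample exclusion threshold.
#' @param de_min_log2cpm,de_min_abs_lfc,de_min_sig DE-selection thresholds.
#' @param alpha adjusted-p significance threshold.
#' @param workdir directory for intermediate files (FASTQ) when
#'   \code{use_reads = TRUE}; defaults to a temporary directory.
#' @param seed master seed (propagated to the cohort config).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            stages = c("synth", "qc", "profiles",
                                       "hemoscore", "diffexpr", "qpcr"),
                            use_reads = FALSE,
                            min_cpm = 2, min_samples = 10L,
                            min_mirna_pct = 15, max_unaligned = 50,
                            strict_qc = TRUE, max_mean_cq = 25,
                            de_min_log2cpm = 5, de_min_abs_lfc = 1,
                            de_min_sig = 3L, alpha = 0.05,
                            workdir = NULL, seed = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  cfg <- list(cohort = cohort, stages = stages, use_reads = use_reads,
              min_cpm = min_cpm, min_samples = min_samples,
              min_mirna_pct = min_mirna_pct, max_unaligned = max_unaligned,
              strict_qc = strict_qc, max_mean_cq = max_mean_cq,
              de_min_log2cpm = de_min_log2cpm,
              de_min_abs_lfc = de_min_abs_lfc, de_min_sig = de_min_sig,
              alpha = alpha, workdir = workdir, seed = cohort$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[setdiff(names(cfg), "workdir")], f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in order -- cohort synthesis (or reads +
#' preprocessing + quantification when \code{use_reads}), sample QC and
#' abundance filtering, diversity/PCA profiling, hemolysis and origin
#' statistics, blocked pairwise differential expression, and qPCR
#' validation statistics -- and returns a machine-readable report stamped
#' with the config hash and seed. A stage failure aborts with the stage
#' name in the error message.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return A nested report list (JSON-serializable via
#'   \code{\link{write_report}}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- config$stages
  report <- list(config_hash = config_hash(config),
                 seed = config$cohort$seed,
                 stages_run = stages)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- run_stage("synth", function() {
    fq <- NULL
    if (config$use_reads) {
      wd <- if (is.null(config$workdir)) tempfile("plasmir_run") else config$workdir
      fq <- file.path(wd, "fastq")
    }
    generate_cohort(config$cohort, fastq_dir = fq)
  })
  counts <- cohort$counts
  meta <- cohort$metadata

  if (config$use_reads) {
    qstage <- run_stage("quantify", function() {
      assignments <- list()
      totals <- integer(0)
      for (s in meta$sample_id) {
        proc <- sub("\\.fastq$", ".proc.fastq", cohort$fastq[[s]])
        st <- preprocess_fastq(cohort$fastq[[s]], proc,
                               adapter = config$cohort$adapter)
        fq <- Biostrings::readDNAStringSet(proc, format = "fastq")
        assignments[[s]] <- assign_reads(as.character(fq), cohort$reference)
        totals[[s]] <- st$input_reads
      }
      count_samples(assignments, cohort$reference, total_reads = totals,
                    metadata = meta[, c("sample_id", "subject_id", "group")])
    })
    counts <- qstage$counts
    meta <- qstage$samples
    meta$degenerate <- cohort$metadata$degenerate[
      match(meta$sample_id, cohort$metadata$sample_id)]
  }

  qc <- run_stage("qc", function()
    sample_qc_gate(meta, config$min_mirna_pct, config$max_unaligned,
                   strict = config$strict_qc))
  keep <- qc$retained
  counts <- counts[, keep, drop = FALSE]
  meta_k <- meta[match(keep, meta$sample_id), ]
  report$qc <- list(
    n_samples_in = nrow(meta), n_samples_retained = length(keep),
    exclusions = qc$exclusions)

  counts_f <- filter_noisy(counts)
  cpm <- cpm_matrix(counts_f)
  expressed <- expression_filter(cpm, config$min_cpm, config$min_samples)
  counts_e <- counts_f[expressed, , drop = FALSE]
  cpm_e <- cpm[expressed, , drop = FALSE]
  l2 <- log2cpm_matrix(cpm_e, is_cpm = TRUE)
  report$filters <- list(n_mirnas_raw = nrow(counts),
                         n_after_noise_filter = nrow(counts_f),
                         n_expressed = length(expressed))

  if ("profiles" %in% stages) {
    report$profiles <- run_stage("profiles", function() {
      div <- diversity_summary(cpm_e)
      div$group <- meta_k$group
      top20 <- vapply(unique(meta_k$group), function(g)
        as.numeric(topn_fraction(cpm_e, meta_k$group, g, 20L)), 0)
      ov <- group_overlap(cpm_e, meta_k$group, config$min_cpm, 2L)
      pca <- pca_profiles(l2, n_components = 2L)
      list(diversity = div, top20_fraction = as.list(top20),
           overlap_regions = as.list(ov$regions),
           overlap_union = ov$union_size,
           pc_variance = pca$var_frac[1:2],
           scores = data.frame(sample_id = rownames(pca$scores),
                               PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                               group = meta_k$group))
    })
  }

  if ("hemoscore" %in% stages) {
    report$hemoscore <- run_stage("hemoscore", function() {
      ab <- cohort$absorbance
      hs <- hemolysis_score(ab$A414, ab$A385)
      names(hs) <- ab$sample_id
      seqratio <- seq_hemolysis_ratio(l2)
      ncpm <- tmm_cpm(counts_e)
      of <- origin_fractions(ncpm, meta_k$group, config$cohort$panels)
      list(hemolysis_score = as.list(hs[keep]),
           hs_group_means = lapply(split(hs[keep], meta_k$group), mean),
           seq_hemolysis_ratio = as.list(seqratio),
           origin_fractions = as.data.frame(of$fractions),
           panel_conflicts = of$panels$conflict_log)
    })
  }

  if ("diffexpr" %in% stages) {
    report$diffexpr <- run_stage("diffexpr", function() {
      de <- fit_pairwise_de(counts_e, meta_k$group, meta_k$subject_id,
                            alpha = config$alpha)
      de <- select_de(de, config$de_min_log2cpm, config$de_min_abs_lfc,
                      config$de_min_sig)
      list(n_contrasts = length(unique(de$contrast)),
           n_significant_comparisons = sum(de$significant),
           de_mirnas = attr(de, "de_mirnas"),
           table = de)
    })
  }

  if ("qpcr" %in% stages) {
    report$qpcr <- run_stage("qpcr", function() {
      excl <- exclude_cq_outliers(cohort$cq, config$max_mean_cq)
      cq <- cohort$cq[, excl$retained, drop = FALSE]
      dcq <- qpcr_hemolysis_dcq(cq)
      rp <- rbc_platelet_ratio(cq)
      ex <- relative_expression(cq)
      nf <- normfinder_stability(
        cq, meta$group[match(colnames(cq), meta$sample_id)])
      seqratio <- seq_hemolysis_ratio(l2)
      conc <- tryCatch(concordance(seqratio, dcq), error = function(e) NULL)
      list(n_retained = length(excl$retained),
           exclusions = excl$log[excl$log$excluded, ],
           dcq = as.list(dcq), rbc_platelet_ratio = as.list(rp),
           normfinder = nf,
           hemolysis_concordance = if (is.null(conc)) NULL else
             conc[c("r_squared", "spearman_rho", "n")])
    })
  }

  class(report) <- "plasmir_report"
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a report from \code{\link{run_pipeline}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 10, dataframe = "columns", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Validate a report against the shipped JSON schema
#'
#' Structural validation against \code{inst/extdata/report-schema.json}:
#' required keys must be present and leaf types must match. Returns TRUE or
#' stops with the offending path.
#'
#' @param report report list or path to a report JSON file.
#' @param schema_path schema location; defaults to the packaged schema.
#' @return TRUE, invisibly, if valid.
#' @export
validate_report <- function(report,
                            schema_path = system.file("extdata",
                                                      "report-schema.json",
                                                      package = "plasmiR")) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(schema_path)
  check <- function(node, sch, path) {
    ty <- sch$type
    ok <- switch(ty,
      object = is.list(node),
      array = is.list(node) || (is.atomic(node) && length(node) != 1),
      number = is.numeric(node) || (is.list(node) && all(vapply(node, is.numeric, TRUE))),
      string = is.character(node),
      boolean = is.logical(node),
      TRUE)
    if (!ok) stop(sprintf("report field '%s' is not of type %s", path, ty),
                  call. = FALSE)
    if (ty == "object") {
      for (req in sch$required)
        if (is.null(node[[req]]))
          stop(sprintf("report is missing required field '%s/%s'", path, req),
               call. = FALSE)
      for (nm in names(sch$properties))
        if (!is.null(node[[nm]]))
          check(node[[nm]], sch$properties[[nm]], paste0(path, "/", nm))
    }
    invisible(TRUE)
  }
  check(unclass(report), schema, "")
  invisible(TRUE)
}
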