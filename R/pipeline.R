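#' End-to-end pipeline: QC, masking, imputation channel, metrics, filters
#'
#' One configuration drives the full run: simulate (or load) genotypes,
#' apply SNP- and sample-level QC, build masking plans, obtain imputed
#' posteriors (from the synthetic channel or from files produced by an
#' external imputer), compute per-SNP metrics and summaries per panel, and
#' apply the configured filters. The run is a pure function of the
#' configuration: repeated invocation is byte-identical.
#'
#' External imputation tools are integrated only through a file contract:
#' an adapter is a function `(masked genotype_matrix, panel_spec) ->
#' posterior_matrix` — typically writing a masked VCF, invoking the tool
#' elsewhere and reading its GEN/VCF-GP output back via [read_imputed()]
#' and [align_alleles()]. No subprocess management lives in the package.
#'
#' @name pipeline
NULL

#' Validate a pipeline configuration
#'
#' @param source `"synthetic"` (the built-in channel over a
#'   [sim_config()]) or `"files"` (truth + imputed read from disk)
#' @param sim a [sim_config()] (synthetic source)
#' @param truth_path,truth_format,imputed_path,imputed_format,imputed_samples
#'   inputs for the file source (see [read_genotypes()], [read_imputed()])
#' @param qc a [qc_thresholds()]; `run_qc = FALSE` skips sample/SNP QC
#' @param run_qc logical
#' @param ancestry optional ancestry-proportion table (data.frame or path
#'   to a tab-delimited file with a `sample` column) for the ancestry
#'   filter; the synthetic source derives one from the simulated admixture
#' @param filters character subset of `c("rsq-threshold",
#'   "post-impute-monomorphic")`
#' @param rsq_threshold threshold for the r2hat filter
#' @param filter_panel which panel defines "monomorphic" for the
#'   post-imputation filter (default `"close"`)
#' @param bin_width MAF bin width
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes tables, summaries and the log there
#' @return validated config list of class `run_config`
#' @export
run_config <- function(source = c("synthetic", "files"),
                       sim = sim_config(),
                       truth_path = NULL, truth_format = "vcf",
                       imputed_path = NULL, imputed_format = "gen-triplet",
                       imputed_samples = NULL,
                       qc = qc_thresholds(), run_qc = TRUE,
                       ancestry = NULL,
                       filters = c("rsq-threshold", "post-impute-monomorphic"),
                       rsq_threshold = 0.3, filter_panel = "close",
                       bin_width = 0.01, out_dir = NULL) {
  source <- match.arg(source)
  stopifnot(all(filters %in% c("rsq-threshold", "post-impute-monomorphic")))
  if (source == "files") {
    if (is.null(truth_path) || is.null(imputed_path)) {
      stop_stage("config", "E_VALIDATE", "file source requires truth_path and imputed_path")
    }
    for (p in c(truth_path, imputed_path)) {
      if (!file.exists(p)) stop_stage("config", "E_VALIDATE", paste("missing input:", p))
    }
  }
  structure(list(source = source, sim = sim,
                 truth_path = truth_path, truth_format = truth_format,
                 imputed_path = imputed_path, imputed_format = imputed_format,
                 imputed_samples = imputed_samples,
                 qc = qc, run_qc = run_qc, ancestry = ancestry,
                 filters = filters, rsq_threshold = rsq_threshold,
                 filter_panel = filter_panel, bin_width = bin_width,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; `sim`, `qc` and
#' `channel` sub-maps are spliced into the respective constructors.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    simargs <- y$sim
    if (!is.null(simargs$channel)) {
      simargs$channel <- do.call(channel_params, simargs$channel)
    }
    y$sim <- do.call(sim_config, simargs)
  }
  if (!is.null(y$qc)) y$qc <- do.call(qc_thresholds, y$qc)
  do.call(run_config, y)
}

#' Run the full evaluation pipeline
#'
#' Stages: inputs -> sample/SNP QC -> panels + masking + channel (synthetic
#' source) or alignment + metrics (file source) -> summaries -> filters.
#' The log records counts at each stage; every summary in the bundle is
#' traceable to the per-SNP tables. Stage failures abort with the stage
#' name and a machine-readable error code.
#'
#' @param config a [run_config()]
#' @return report bundle (class `run_bundle`): qc_report, panels, plans,
#'   metrics, summaries, filtered, log
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (config$source == "synthetic") {
    scen <- scenario_three_panels(config$sim)
    truth <- scen$truth
    metrics <- scen$metrics
    summaries <- scen$summaries
    panels <- scen$panels
    plans <- scen$plans
    note("synthetic scenario: %d SNPs (%d planted), %d samples",
         config$sim$n_snps, length(scen$planted_vids), config$sim$n_samples)

    qc_report <- NULL
    if (config$run_qc) {
      info <- attr(truth, "sample_info")
      anc_tab <- config$ancestry %||%
        data.frame(sample = info$sample, African = info$african,
                   European = info$european)
      qc_report <- pipeline_qc(subset_genotypes(truth, scen$chip_vids),
                               anc_tab, config$qc, note)
    }
  } else {
    truth <- read_genotypes(config$truth_path, config$truth_format)
    note("truth: %d variants x %d samples", nrow(truth$calls), ncol(truth$calls))
    imputed <- read_imputed(config$imputed_path, config$imputed_format,
                            samples = config$imputed_samples)
    imputed <- align_alleles(imputed, truth)
    ac <- attr(imputed, "align_counts")
    note("aligned: kept %d (swapped %d), excluded %d ambiguous / %d mismatch / %d unmatched",
         ac[["kept"]], ac[["swapped"]], ac[["ambiguous_excluded"]],
         ac[["mismatch_excluded"]], ac[["unmatched"]])
    qc_report <- NULL
    if (config$run_qc) {
      anc_tab <- config$ancestry
      if (is.character(anc_tab)) {
        anc_tab <- utils::read.delim(anc_tab, stringsAsFactors = FALSE)
      }
      qc_report <- pipeline_qc(truth, anc_tab, config$qc, note)
    }
    # one evaluation set = one repetition; r2hat falls back to all rows
    tab <- snp_metrics(imputed, truth = truth, rep = 1L)
    metrics <- list(imputed = tab)
    summaries <- list(imputed = summarize_metrics(tab, bin_width = config$bin_width))
    panels <- NULL
    plans <- NULL
  }

  filtered <- list()
  for (pn in names(metrics)) {
    ftab <- list()
    if ("rsq-threshold" %in% config$filters) {
      fr <- rsq_threshold_filter(metrics[[pn]], config$rsq_threshold)
      kept <- metrics[[pn]][metrics[[pn]]$vid %in% fr$kept_vids, , drop = FALSE]
      ftab[["rsq-threshold"]] <- list(
        filter = fr,
        summary = if (nrow(kept)) summarize_metrics(kept, plans, config$bin_width) else NULL)
      note("%s / rsq>=%g: kept %d, removed %d", pn, config$rsq_threshold,
           length(fr$kept_vids), length(fr$removed_vids))
    }
    if ("post-impute-monomorphic" %in% config$filters && !is.null(panels)) {
      pf <- post_impute_filter(metrics[[pn]], panels[[config$filter_panel]],
                               plans, config$bin_width)
      ftab[["post-impute-monomorphic"]] <- pf
      note("%s / monomorphic-in-%s: kept %d, removed %d", pn,
           config$filter_panel, length(pf$filter$kept_vids),
           length(pf$filter$removed_vids))
    }
    filtered[[pn]] <- ftab
  }

  bundle <- structure(list(config = config, qc_report = qc_report,
                           panels = panels, plans = plans, metrics = metrics,
                           summaries = summaries, filtered = filtered,
                           log = log),
                      class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Sample- then SNP-level QC with stagewise bookkeeping.
pipeline_qc <- function(g, ancestry, thresholds, note) {
  steps <- list()
  n0 <- length(g$samples)
  dup <- duplicate_prune(g, thresholds)
  steps$duplicates <- list(removed = dup$removed, n_removed = length(dup$removed))
  g <- genotype_matrix(g$variants, dup$retained,
                       g$calls[, dup$retained, drop = FALSE])
  kin <- kinship_prune(g, thresholds)
  steps$relatedness <- list(removed = kin$removed, n_removed = length(kin$removed))
  g <- genotype_matrix(g$variants, kin$retained,
                       g$calls[, kin$retained, drop = FALSE])
  if (!is.null(ancestry)) {
    anc <- ancestry[ancestry$sample %in% g$samples, , drop = FALSE]
    af <- ancestry_filter(anc, thresholds)
    steps$ancestry <- list(removed = af$removed, n_removed = length(af$removed))
    g <- genotype_matrix(g$variants, af$retained,
                         g$calls[, af$retained, drop = FALSE])
  }
  sq <- snp_qc(g, thresholds)
  note("qc: %d -> %d samples, %d -> %d SNPs", n0, length(g$samples),
       nrow(g$calls), sq$report$retained[["variants"]])
  list(subjects = steps, snps = sq$report,
       retained = c(samples = length(g$samples),
                    variants = sq$report$retained[["variants"]]))
}

#' Write a run bundle to disk
#'
#' Per-SNP metrics as TSV, summaries as JSON, MAF-bin tables as TSV,
#' exclusion lists for filtered variants, the QC report as JSON and the
#' stage log as text.
#'
#' @param bundle a [run_pipeline()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pn in names(bundle$metrics)) {
    write_metrics(bundle$metrics[[pn]], file.path(dir, paste0("metrics_", pn, ".tsv")))
    write_summary(bundle$summaries[[pn]], file.path(dir, paste0("summary_", pn, ".json")))
    utils::write.table(bundle$summaries[[pn]]$binned,
                       file.path(dir, paste0("bins_", pn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (fn in names(bundle$filtered[[pn]])) {
      f <- bundle$filtered[[pn]][[fn]]$filter
      write_exclusion_list(f$removed_vids,
                           file.path(dir, paste0("excluded_", pn, "_", fn, ".txt")))
    }
  }
  if (!is.null(bundle$qc_report)) {
    write_qc_report(bundle$qc_report, file.path(dir, "qc_report.json"))
  }
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Compare evaluation summaries across panels / filters
#'
#' Long-format comparison keyed by (panel, filter): pooled concordance and
#' IQS, mean r2hat, stratum quantities and SNP counts; the per-bin r2hat
#' tables are stacked alongside for plotting the r2hat-vs-MAF profile.
#'
#' @param summaries named list of [summarize_metrics()] results (one per
#'   panel or per panel x filter cell); names become the `panel` key
#' @return list with `table` (one row per summary) and `bins` (stacked
#'   per-bin rows), both data.frames
#' @export
compare_summaries <- function(summaries) {
  stopifnot(length(summaries) >= 2)
  bw <- unique(vapply(summaries, `[[`, numeric(1), "bin_width"))
  if (length(bw) != 1) stop("mismatched MAF bin widths across summaries")
  tab <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(panel = nm,
               concordance = unname(s$pooled["concordance"]),
               iqs = unname(s$pooled["iqs"]),
               rsq_mean = s$rsq_mean,
               rsq_le2 = maf_stratum_rsq(s, 0.02, above = FALSE),
               rsq_gt2 = maf_stratum_rsq(s, 0.02, above = TRUE),
               frac_maf_le2 = maf_stratum_fraction(s, 0.02),
               n_polymorphic = unname(s$counts["n_polymorphic"]),
               stringsAsFactors = FALSE)
  }))
  bins <- do.call(rbind, lapply(names(summaries), function(nm) {
    b <- summaries[[nm]]$binned
    b$panel <- nm
    b
  }))
  list(table = tab, bins = bins)
}

#' Plot per-bin r2hat against MAF across panels
#'
#' Optional visual aid (requires ggplot2); never load-bearing for any
#' numerical result.
#'
#' @param comparison a [compare_summaries()] result
#' @return a ggplot object
#' @export
plot_rsq_bins <- function(comparison) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rsq_bins requires the ggplot2 package")
  }
  b <- comparison$bins
  b <- b[b$n > 0, , drop = FALSE]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$maf_hi, y = .data$rsq_mean,
                                  colour = .data$panel)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "minor allele frequency (bin upper bound)",
                  y = expression(mean ~ hat(r)^2),
                  colour = "panel") +
    ggplot2::theme_minimal()
}
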