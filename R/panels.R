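#' Reference-panel composition and population-specific SNP filtering
#'
#' A reference panel is a named combination of populations with sample
#' counts and per-population ALT-allele frequencies. Pooled panel
#' frequencies are count-weighted means, so a SNP segregating in any member
#' population is polymorphic in the panel. SNPs monomorphic in a subpanel
#' of interest (pooled frequency exactly 0 or 1 — fixed ALT counts too) are
#' population-specific elsewhere and can be filtered before or after
#' imputation.
#'
#' @name panels
NULL

#' Population sample counts, 1000-Genomes-style (February 2012 release)
#'
#' The fourteen populations and sample counts used to build the three
#' nested panels: the close 3-population panel (YRI+CEU+ASW, N = 234), the
#' 8-population African/European panel (N = 625) and the full cosmopolitan
#' panel (N = 1092).
#'
#' @return data.frame with columns code, count, group
#' @export
kg_populations <- function() {
  data.frame(
    code = c("YRI", "CEU", "ASW", "LWK", "FIN", "GBR", "IBS", "TSI",
             "CLM", "MXL", "PUR", "CHB", "CHS", "JPT"),
    count = c(88L, 85L, 61L, 97L, 93L, 89L, 14L, 98L,
              60L, 66L, 55L, 97L, 100L, 89L),
    group = c("close", "close", "close", "afr_eur", "afr_eur", "afr_eur",
              "afr_eur", "afr_eur", "all", "all", "all", "all", "all", "all"),
    stringsAsFactors = FALSE
  )
}

#' Member populations of the three nested panels
#' @param which `"close"`, `"afr_eur"` or `"all"`
#' @return data.frame with columns code, count
#' @export
panel_members <- function(which = c("close", "afr_eur", "all")) {
  which <- match.arg(which)
  pops <- kg_populations()
  keep <- switch(which,
                 close = pops$group == "close",
                 afr_eur = pops$group %in% c("close", "afr_eur"),
                 all = rep(TRUE, nrow(pops)))
  pops[keep, c("code", "count")]
}

#' Compose a reference panel from member populations
#'
#' Pooled panel ALT frequency per variant is the sample-count-weighted mean
#' of the member-population frequencies (haplotype counts are 2 x samples,
#' so count weighting and haplotype weighting coincide).
#'
#' @param name panel label
#' @param members data.frame with columns code, count (counts positive), or
#'   a named integer vector
#' @param af_source per-population ALT-frequency table: data.frame with a
#'   `vid` column plus one numeric column per population (or a matrix with
#'   vid rownames)
#' @return list of class `panel_spec` with fields name, populations, af,
#'   pooled, n_total
#' @export
compose_panel <- function(name, members, af_source) {
  if (!is.data.frame(members)) {
    members <- data.frame(code = names(members), count = as.integer(members),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(members$count > 0))
  if (is.data.frame(af_source)) {
    vids <- af_source$vid
    af <- as.matrix(af_source[, setdiff(names(af_source), "vid"), drop = FALSE])
    rownames(af) <- vids
  } else {
    af <- as.matrix(af_source)
  }
  missing_pop <- setdiff(members$code, colnames(af))
  if (length(missing_pop)) {
    stop("unknown population code(s) in panel '", name, "': ",
         paste(missing_pop, collapse = ", "))
  }
  af <- af[, members$code, drop = FALSE]
  if (any(af < 0 | af > 1, na.rm = TRUE)) stop("allele frequencies must be in [0, 1]")
  w <- members$count / sum(members$count)
  pooled <- as.numeric(af %*% w)
  names(pooled) <- rownames(af)
  structure(list(name = name, populations = members, af = af,
                 pooled = pooled, n_total = sum(members$count)),
            class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("panel_spec '%s': %d populations, N = %d, %d variants\n",
              x$name, nrow(x$populations), x$n_total, length(x$pooled)))
  invisible(x)
}

#' Variants monomorphic in a panel
#'
#' Pooled panel ALT frequency exactly 0 or exactly 1 (a fixed ALT allele is
#' just as non-segregating as an absent one).
#'
#' @param panel a [compose_panel()] result
#' @return character vector of variant ids
#' @export
monomorphic_set <- function(panel) {
  names(panel$pooled)[panel$pooled == 0 | panel$pooled == 1]
}

filter_result <- function(kept, removed, reason) {
  structure(list(kept_vids = kept, removed_vids = removed, reason = reason),
            class = "filter_result")
}

#' Pre-imputation filter: drop reference SNPs monomorphic in a subpanel
#'
#' Removes from the reference SNP set every variant monomorphic in the
#' target subpanel (the panel of interest for the study population) before
#' imputation is run. Variants not covered by the subpanel's frequency
#' table are treated as monomorphic there (frequency 0) and removed too.
#'
#' @param reference_vids reference SNP identifiers
#' @param target_panel the subpanel of interest
#' @return a `filter_result` (kept_vids, removed_vids, reason)
#' @export
pre_impute_filter <- function(reference_vids, target_panel) {
  mono <- monomorphic_set(target_panel)
  uncovered <- setdiff(reference_vids, names(target_panel$pooled))
  removed <- intersect(reference_vids, union(mono, uncovered))
  kept <- setdiff(reference_vids, removed)
  if (!length(kept)) {
    warning("degenerate input: every reference SNP is monomorphic in panel '",
            target_panel$name, "'")
  }
  filter_result(kept, removed, "monomorphic-in-subpanel")
}

#' Post-imputation filter: drop imputed SNPs monomorphic in a subpanel
#'
#' SNPs are imputed from the full reference and those monomorphic in the
#' panel of interest are removed afterwards; the evaluation summary is
#' recomputed on the remainder.
#'
#' @param metrics a [snp_metrics()] data.frame
#' @param target_panel the subpanel of interest
#' @param plans optional mask plans forwarded to [summarize_metrics()]
#' @param bin_width MAF bin width for the recomputed summary
#' @return list with `filter` (a `filter_result`) and `summary`
#' @export
post_impute_filter <- function(metrics, target_panel, plans = NULL,
                               bin_width = 0.01) {
  stopifnot(nrow(metrics) >= 1)
  mono <- monomorphic_set(target_panel)
  uncovered <- setdiff(metrics$vid, names(target_panel$pooled))
  drop <- metrics$vid %in% union(mono, uncovered)
  res <- filter_result(unique(metrics$vid[!drop]), unique(metrics$vid[drop]),
                       "monomorphic-in-subpanel")
  kept <- metrics[!drop, , drop = FALSE]
  summary <- if (nrow(kept)) summarize_metrics(kept, plans, bin_width) else NULL
  list(filter = res, summary = summary)
}

#' r2hat threshold filter
#'
#' Keeps SNPs with estimated r2hat at or above the threshold (inclusive:
#' a SNP at exactly 0.3 under the conventional `r2 >= 0.3` rule survives).
#' Rows with undefined r2hat are removed.
#'
#' @param metrics a [snp_metrics()] data.frame
#' @param threshold minimum r2hat (default 0.3)
#' @return a `filter_result` with reason `"rsq-below-threshold"`
#' @export
rsq_threshold_filter <- function(metrics, threshold = 0.3) {
  stopifnot(nrow(metrics) >= 1)
  keep <- !is.na(metrics$rsq_est) & metrics$rsq_est >= threshold
  filter_result(unique(metrics$vid[keep]), unique(metrics$vid[!keep]),
                "rsq-below-threshold")
}

#' Write a variant exclusion list (one id per line)
#'
#' The format consumed by external imputation tools' exclusion options.
#' @param vids variant identifiers
#' @param path output file
#' @return `path`, invisibly
#' @export
write_exclusion_list <- function(vids, path) {
  writeLines(vids, path)
  invisible(path)
}
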