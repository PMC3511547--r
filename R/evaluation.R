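#' Masked-SNP evaluation harness and imputation performance metrics
#'
#' The evaluation design: hide a fraction of genotyped SNPs, impute them,
#' and compare the most-likely imputed genotypes against the hidden truth.
#' Three metrics are computed per SNP: concordance (fraction of agreeing
#' calls), IQS (concordance corrected for chance agreement, kappa-style —
#' informative at low minor allele frequency where raw concordance is
#' inflated), and r2hat (squared correlation between imputed dosage and
#' truth; the variance-ratio form needs no truth and so extends to every
#' imputed SNP).
#'
#' @name evaluation
NULL

#' Build randomized masking plans
#'
#' Repetition `r` masks `round(fraction * M)` of the eligible variants
#' (rounding half away from zero), sampled without replacement under seed
#' `base_seed + r`. Plans are independent across repetitions (overlap is
#' allowed) and bit-reproducible for fixed seeds.
#'
#' @param vids eligible variant identifiers
#' @param fraction fraction of variants to mask per repetition (default 2%)
#' @param reps number of repetitions (default 10)
#' @param base_seed integer seed offset
#' @return list of `mask_plan` objects (fields rep, seed, fraction,
#'   masked_vids)
#' @export
build_mask_plans <- function(vids, fraction = 0.02, reps = 10, base_seed = 1) {
  stopifnot(fraction > 0, fraction < 1, reps >= 1, length(vids) >= 1)
  k <- round_half_away(fraction * length(vids))
  if (k == 0) stop("degenerate plan: fraction * length(vids) rounds to zero")
  lapply(seq_len(reps), function(r) {
    seed <- (as.numeric(base_seed) + r) %% .Machine$integer.max
    masked <- with_seed(seed, sample(vids, k))
    structure(list(rep = r, seed = seed, fraction = fraction,
                   masked_vids = masked),
              class = "mask_plan")
  })
}

#' Most likely discrete genotype from a posterior triplet
#'
#' Argmax of (p0, p1, p2); ties break toward the smallest genotype index
#' (ties have measure zero for real posteriors; the rule exists for
#' determinism).
#'
#' @param p numeric triplet, or a matrix with 3 columns (one triplet per row)
#' @return genotype in \{0, 1, 2\} (vector for matrix input)
#' @export
most_likely_genotype <- function(p) {
  if (is.matrix(p)) return(max.col(p, ties.method = "first") - 1L)
  which.max(p) - 1L
}

#' Most likely genotypes for a whole posterior matrix
#' @param p a [posterior_matrix()]
#' @return integer matrix (variants x samples) of genotypes in \{0, 1, 2\}
#' @export
hard_calls <- function(p) {
  g <- (p$p1 > p$p0) + 0L
  g[p$p2 > p$p0 & p$p2 > p$p1] <- 2L
  dimnames(g) <- dimnames(p$p0)
  g
}

#' 3x3 truth-by-imputed contingency table
#'
#' Rows index the true genotype, columns the most-likely imputed genotype.
#' Pairs with missing truth are excluded.
#'
#' @param truth integer vector of true genotypes (NA = missing)
#' @param imputed integer vector of most-likely imputed genotypes
#' @return 3x3 integer matrix of class `contingency3`
#' @export
contingency <- function(truth, imputed) {
  stopifnot(length(truth) == length(imputed))
  ok <- !is.na(truth)
  if (!any(ok)) stop("undefined table: no usable genotype pairs")
  tab <- table(factor(truth[ok], levels = 0:2),
               factor(imputed[ok], levels = 0:2))
  structure(matrix(as.integer(tab), 3, 3,
                   dimnames = list(truth = 0:2, imputed = 0:2)),
            class = c("contingency3", "matrix"))
}

#' Concordance rate of a contingency table
#' @param t 3x3 contingency table (truth x imputed)
#' @return trace / total, in [0, 1]
#' @export
concordance <- function(t) {
  n <- sum(t)
  stopifnot(n >= 1)
  sum(diag(t)) / n
}

#' Imputation quality score (chance-corrected concordance)
#'
#' `IQS = (P0 - Pc) / (1 - Pc)` with `P0` the observed agreement (trace/n)
#' and `Pc` the chance agreement, the sum of products of marginal genotype
#' frequencies — the agreement expected if genotypes were called at random
#' with the same margins (Cohen's kappa on the 3x3 table). Undefined (NA)
#' when `Pc = 1`, i.e. both margins are concentrated on one genotype.
#'
#' @param t 3x3 contingency table (truth x imputed)
#' @return value in [-1, 1], or NA when undefined
#' @export
iqs <- function(t) {
  n <- sum(t)
  stopifnot(n >= 1)
  rs <- rowSums(t)
  cs <- colSums(t)
  chance <- sum(as.numeric(rs) * as.numeric(cs))   # = Pc * n^2, exact in doubles
  if (chance == as.numeric(n)^2) return(NA_real_)
  p0 <- sum(diag(t)) / n
  pc <- chance / n^2
  (p0 - pc) / (1 - pc)
}

#' Estimated r2hat from dosages alone (variance-ratio form)
#'
#' `p_hat = mean(d) / 2`; `r2hat = Var(d) / (2 p_hat (1 - p_hat))`, clipped
#' to [0, 1], where Var uses the divide-by-n form. Under Hardy-Weinberg the
#' denominator is the variance of a perfectly imputed genotype, so r2hat
#' estimates the squared correlation with the unobserved truth — computable
#' for every imputed SNP, truth or no truth. Returns 0 for monomorphic
#' dosages (`p_hat` 0 or 1) and for constant dosages.
#'
#' @param d numeric dosages in [0, 2] for one SNP (>= 2 samples)
#' @return value in [0, 1]
#' @export
estimated_rsq <- function(d) {
  d <- d[!is.na(d)]
  stopifnot(length(d) >= 2)
  p <- mean(d) / 2
  if (p <= 0 || p >= 1) return(0)
  v <- mean(d^2) - mean(d)^2
  clip01(v / (2 * p * (1 - p)))
}

#' True r2: squared correlation of dosage with the true genotype
#'
#' Computable only where truth exists (masked SNPs). Pairs with missing
#' truth are excluded; NA when fewer than 2 usable pairs remain or either
#' vector is constant.
#'
#' @param d numeric dosages
#' @param g integer true genotypes (NA = missing)
#' @return squared Pearson correlation in [0, 1], or NA
#' @export
true_rsq <- function(d, g) {
  stopifnot(length(d) == length(g))
  ok <- !is.na(g) & !is.na(d)
  if (sum(ok) < 2) return(NA_real_)
  d <- d[ok]; g <- g[ok]
  if (stats::sd(d) == 0 || stats::sd(g) == 0) return(NA_real_)
  r2 <- stats::cor(d, g)^2
  # cor(x, x) can return 1 - eps; a perfectly correlated pair is exactly 1
  if (r2 > 1 - 1e-12) r2 <- 1
  clip01(r2)
}

#' Per-SNP metrics for a set of variants
#'
#' For each requested variant: the 3x3 table of truth vs most-likely
#' imputed genotype, concordance, IQS, r2hat (from dosages), true r2 and
#' the MAF used for binning. Masked SNPs use truth-derived MAF; SNPs
#' without truth use the dosage-estimated MAF (the best information
#' available for each class).
#'
#' @param imputed a [posterior_matrix()]
#' @param truth optional [genotype_matrix()] covering (some of) the same
#'   variants; metrics needing truth are NA elsewhere
#' @param vids variants to evaluate (default: all imputed variants)
#' @param rep repetition index recorded in the output (NA for the
#'   full-imputation table)
#' @return data.frame of class `snp_metrics` with columns vid, chrom, pos,
#'   rep, maf, n_eval, concordance, iqs, rsq_est, rsq_true
#' @export
snp_metrics <- function(imputed, truth = NULL, vids = NULL, rep = NA_integer_) {
  vids <- vids %||% imputed$variants$vid
  iv <- match(vids, imputed$variants$vid)
  stopifnot(!anyNA(iv))
  d <- dosages(imputed)
  hc <- hard_calls(imputed)
  tvx <- if (!is.null(truth)) match(vids, truth$variants$vid) else rep(NA_integer_, length(vids))

  out <- data.frame(vid = vids,
                    chrom = imputed$variants$chrom[iv],
                    pos = imputed$variants$pos[iv],
                    rep = rep,
                    maf = NA_real_, n_eval = 0L,
                    concordance = NA_real_, iqs = NA_real_,
                    rsq_est = NA_real_, rsq_true = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(vids)) {
    di <- d[iv[k], ]
    ph <- mean(di) / 2
    out$rsq_est[k] <- estimated_rsq(di)
    out$maf[k] <- min(ph, 1 - ph)
    if (!is.na(tvx[k])) {
      g <- truth$calls[tvx[k], ]
      ok <- !is.na(g)
      out$n_eval[k] <- sum(ok)
      if (any(ok)) {
        tab <- contingency(g, hc[iv[k], ])
        out$concordance[k] <- concordance(tab)
        out$iqs[k] <- iqs(tab)
        out$rsq_true[k] <- true_rsq(di, g)
        p_t <- mean(g[ok]) / 2
        out$maf[k] <- min(p_t, 1 - p_t)   # truth-derived MAF when available
      }
    }
  }
  class(out) <- c("snp_metrics", "data.frame")
  out
}

#' Mark monomorphic-dosage rows (excluded from r2hat averages)
#' @noRd
is_polymorphic_row <- function(metrics) {
  !is.na(metrics$maf) & metrics$maf > 0
}

#' Summarize per-SNP metrics into the study-level report
#'
#' Averaging follows the masked-SNP design: concordance and IQS are averaged
#' per repetition over that repetition's masked SNPs, then across
#' repetitions (pooled). r2hat is averaged over all polymorphic imputed
#' SNPs — rows with `rep = NA`, i.e. the full-imputation table, falling back
#' to all rows when no such rows exist; monomorphic-dosage SNPs are
#' excluded and counted. MAF bins are half-open intervals (0, 0.01],
#' (0.01, 0.02], ..., (0.49, 0.5], so a SNP at exactly 2% falls in the
#' (0.01, 0.02] bin (the boundary of the low-frequency stratum). Undefined
#' metrics are excluded from averages and reported as counts, never imputed
#' as zero.
#'
#' @param per_snp a [snp_metrics()] data.frame (may mix per-rep masked rows
#'   and `rep = NA` full-imputation rows)
#' @param plans optional list of mask plans (used to order/verify reps)
#' @param bin_width MAF bin width (default 1%)
#' @return list of class `evaluation_summary` with per_rep, pooled,
#'   rsq_mean, binned, counts
#' @export
summarize_metrics <- function(per_snp, plans = NULL, bin_width = 0.01) {
  stopifnot(nrow(per_snp) >= 1)
  masked <- per_snp[!is.na(per_snp$rep), , drop = FALSE]
  reps <- if (!is.null(plans)) vapply(plans, `[[`, integer(1), "rep") else
    sort(unique(masked$rep))
  per_rep <- data.frame(rep = as.integer(reps),
                        concordance = rep(NA_real_, length(reps)),
                        iqs = rep(NA_real_, length(reps)),
                        n_snps = rep(0L, length(reps)))
  for (i in seq_along(reps)) {
    rows <- masked[masked$rep == reps[i], , drop = FALSE]
    per_rep$n_snps[i] <- nrow(rows)
    if (nrow(rows)) {
      per_rep$concordance[i] <- mean(rows$concordance, na.rm = TRUE)
      per_rep$iqs[i] <- mean(rows$iqs, na.rm = TRUE)
    }
  }
  pooled <- c(concordance = mean(per_rep$concordance, na.rm = TRUE),
              iqs = mean(per_rep$iqs, na.rm = TRUE))

  rsq_rows <- per_snp[is.na(per_snp$rep), , drop = FALSE]
  if (!nrow(rsq_rows)) rsq_rows <- per_snp
  poly <- rsq_rows[is_polymorphic_row(rsq_rows) & !is.na(rsq_rows$rsq_est), ,
                   drop = FALSE]
  rsq_mean <- if (nrow(poly)) mean(poly$rsq_est) else NA_real_

  breaks <- seq(0, 0.5, by = bin_width)
  bin <- cut(poly$maf, breaks = breaks, right = TRUE, include.lowest = FALSE)
  binned <- data.frame(bin = levels(bin),
                       maf_hi = breaks[-1],
                       n = as.integer(table(bin)),
                       rsq_mean = as.numeric(tapply(poly$rsq_est, bin, mean)),
                       stringsAsFactors = FALSE)
  counts <- c(n_masked_rows = nrow(masked),
              n_undefined_iqs = sum(is.na(masked$iqs)),
              n_undefined_concordance = sum(is.na(masked$concordance)),
              n_imputed = nrow(rsq_rows),
              n_polymorphic = nrow(poly),
              n_monomorphic_excluded = nrow(rsq_rows) - nrow(poly))
  structure(list(per_rep = per_rep, pooled = pooled, rsq_mean = rsq_mean,
                 binned = binned, counts = counts, bin_width = bin_width),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("evaluation_summary: %d reps | pooled concordance %.4f, IQS %.4f | mean r2hat %.4f over %d polymorphic SNPs\n",
              nrow(x$per_rep), x$pooled[["concordance"]], x$pooled[["iqs"]],
              x$rsq_mean, x$counts[["n_polymorphic"]]))
  invisible(x)
}

#' Fraction of polymorphic imputed SNPs at or below a MAF cutoff
#'
#' Computed from the binned table, so the cutoff must be a bin boundary
#' (e.g. 0.02 with 1% bins: the low-frequency stratum is MAF <= 2%,
#' inclusive).
#'
#' @param summary an [summarize_metrics()] result
#' @param maf_cutoff stratum boundary (default 0.02)
#' @return fraction in [0, 1]
#' @export
maf_stratum_fraction <- function(summary, maf_cutoff = 0.02) {
  b <- summary$binned
  stopifnot(any(abs(b$maf_hi - maf_cutoff) < 1e-12))
  sum(b$n[b$maf_hi <= maf_cutoff + 1e-12]) / sum(b$n)
}

#' Mean r2hat inside / above a MAF stratum
#' @param summary an [summarize_metrics()] result
#' @param maf_cutoff stratum boundary (default 0.02)
#' @param above if TRUE, average over bins with MAF > cutoff
#' @return weighted mean r2hat for the stratum (NA if empty)
#' @export
maf_stratum_rsq <- function(summary, maf_cutoff = 0.02, above = FALSE) {
  b <- summary$binned
  sel <- if (above) b$maf_hi > maf_cutoff + 1e-12 else b$maf_hi <= maf_cutoff + 1e-12
  sel <- sel & b$n > 0
  if (!any(sel)) return(NA_real_)
  sum(b$rsq_mean[sel] * b$n[sel]) / sum(b$n[sel])
}

#' Write per-SNP metrics as a tab-delimited table
#' @param metrics a [snp_metrics()] data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an evaluation summary as JSON
#' @param summary an [summarize_metrics()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
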