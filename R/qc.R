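#' Quality-control thresholds
#'
#' Defaults follow standard genome-wide association practice: remove SNPs
#' with minor allele frequency below 1%, call rate below 95% or an exact
#' Hardy-Weinberg p-value below 1e-4; treat sample pairs with identity-by-
#' state above 99% as duplicates; treat pairwise kinship above 0.0441 (the
#' third-degree-relative cutoff of the stratification-robust estimator) as
#' related; and require at least 60% African ancestry for an admixed
#' African-American study sample.
#'
#' @param maf_min minimum minor allele frequency (strict: remove if below)
#' @param call_rate_min minimum per-SNP call rate
#' @param hwe_p_min minimum exact Hardy-Weinberg p-value
#' @param ibs_dup identity-by-state above which a pair is a duplicate
#' @param kinship_max kinship coefficient above which a pair is related
#' @param african_ancestry_min minimum African ancestry fraction
#' @return a list of class `qc_thresholds`
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.95,
                          hwe_p_min = 1e-4, ibs_dup = 0.99,
                          kinship_max = 0.0441, african_ancestry_min = 0.60) {
  t <- list(maf_min = maf_min, call_rate_min = call_rate_min,
            hwe_p_min = hwe_p_min, ibs_dup = ibs_dup,
            kinship_max = kinship_max,
            african_ancestry_min = african_ancestry_min)
  stopifnot(all(unlist(t) >= 0), all(unlist(t) <= 1))
  structure(t, class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: with the allele counts fixed, the
#' probabilities of all heterozygote counts of the same parity are computed
#' and those no more probable than the observed count are summed (the
#' behavior of the standard exact implementations used for GWAS QC; a
#' chi-square test misbehaves exactly where the filter matters, at low MAF).
#' A relative guard of 1e-7 on the "no more probable" comparison makes tie
#' inclusion robust to floating-point rounding.
#'
#' @param n0,n1,n2 counts of genotypes with 0, 1 and 2 copies of one allele
#' @return two-sided p-value in (0, 1]; 1.0 for monomorphic sites
#' @export
hwe_exact_pvalue <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) < 0)) stop("genotype counts must be non-negative")
  n <- n0 + n1 + n2
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n0 + n1
  na <- 2 * n2 + n1
  if (nA == 0 || na == 0) return(1.0)
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # exact probability of each heterozygote count given allele counts
  lp <- hets * log(2) + lfactorial(n) -
    lfactorial((nA - hets) / 2) - lfactorial(hets) - lfactorial((na - hets) / 2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  pr <- exp(lp)
  pobs <- pr[match(n1, hets)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#' Per-SNP quality-control filter
#'
#' Removes variants failing any of the three criteria, with strict
#' inequalities: MAF < `maf_min`, call rate < `call_rate_min`, or exact HWE
#' p-value < `hwe_p_min`. MAF and HWE are computed on non-missing calls. A
#' variant may count against several filters; the report tallies each.
#'
#' @param g a [genotype_matrix()]
#' @param t a [qc_thresholds()]
#' @return list with elements `genotypes` (filtered matrix) and `report`
#'   (per-filter removal counts and retained dimensions)
#' @export
snp_qc <- function(g, t = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$calls) >= 1)
  maf <- maf_from_calls(g)
  cr <- call_rate(g)
  hwe <- apply(g$calls, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(1.0)
    hwe_exact_pvalue(sum(row == 0L), sum(row == 1L), sum(row == 2L))
  })
  fail_maf <- is.na(maf) | maf < t$maf_min
  fail_cr <- cr < t$call_rate_min
  fail_hwe <- hwe < t$hwe_p_min
  drop <- fail_maf | fail_cr | fail_hwe
  keep <- which(!drop)
  gz <- genotype_matrix(g$variants[keep, , drop = FALSE], g$samples,
                        g$calls[keep, , drop = FALSE])
  report <- list(
    snps_removed = c(maf = sum(fail_maf), call_rate = sum(fail_cr),
                     hwe = sum(fail_hwe), total = sum(drop)),
    removed_vids = g$variants$vid[drop],
    retained = c(variants = length(keep), samples = length(g$samples))
  )
  list(genotypes = gz, report = report)
}

#' Pairwise identity-by-state
#'
#' Per-allele sharing averaged over co-called variants:
#' `mean((2 - |g_i - g_j|) / 2)`. A sample against itself gives exactly 1.
#'
#' @param g a [genotype_matrix()]
#' @return symmetric samples x samples matrix (NA where no co-called SNPs)
#' @export
ibs_matrix <- function(g) {
  calls <- g$calls
  s <- ncol(calls)
  out <- matrix(NA_real_, s, s, dimnames = list(g$samples, g$samples))
  for (i in seq_len(s)) {
    gi <- calls[, i]
    for (j in i:s) {
      ok <- !is.na(gi) & !is.na(calls[, j])
      out[i, j] <- out[j, i] <-
        if (any(ok)) mean((2 - abs(gi[ok] - calls[ok, j])) / 2) else NA_real_
    }
  }
  out
}

#' Stratification-robust pairwise kinship
#'
#' The between-family robust estimator computed from heterozygote and
#' opposite-homozygote counts over co-called SNPs:
#' `phi = (N_het,het - 2 N_AA,aa) / (N_het(i) + N_het(j))`.
#' Identical genotype vectors give exactly 0.5; unrelated samples are near
#' 0; the estimator is robust to population stratification, unlike plain
#' identity-by-descent estimates.
#'
#' @param g a [genotype_matrix()]
#' @return symmetric samples x samples kinship matrix (diagonal 0.5; NA when
#'   neither sample carries a heterozygote)
#' @export
kinship_matrix <- function(g) {
  calls <- g$calls
  s <- ncol(calls)
  out <- matrix(NA_real_, s, s, dimnames = list(g$samples, g$samples))
  for (i in seq_len(s)) {
    gi <- calls[, i]
    for (j in i:s) {
      gj <- calls[, j]
      ok <- !is.na(gi) & !is.na(gj)
      a <- gi[ok]; b <- gj[ok]
      den <- sum(a == 1L) + sum(b == 1L)
      out[i, j] <- out[j, i] <- if (den == 0) NA_real_ else
        (sum(a == 1L & b == 1L) - 2 * sum(abs(a - b) == 2L)) / den
    }
  }
  out
}

# Shared pruning logic: cluster sample pairs exceeding `threshold` under
# `pairwise`, keep the highest-call-rate member of each cluster (ties broken
# by lexicographically smallest id).
prune_by_pairs <- function(g, pairwise, threshold) {
  s <- g$samples
  idx <- which(upper.tri(pairwise) & !is.na(pairwise) & pairwise > threshold,
               arr.ind = TRUE)
  pairs <- cbind(s[idx[, 1]], s[idx[, 2]])
  comps <- components_from_pairs(s, pairs)
  cr <- colMeans(!is.na(g$calls))
  names(cr) <- s
  keep <- vapply(comps, function(cm) {
    cm <- sort(cm)                      # lexicographic tie-break
    cm[which.max(cr[cm])]
  }, character(1))
  keep <- s[s %in% keep]                # preserve input order
  list(retained = keep, removed = setdiff(s, keep))
}

#' Duplicate-sample pruning by identity-by-state
#'
#' Pairs with IBS above `ibs_dup` are linked; within each connected
#' component only the sample with the highest call rate is retained (ties
#' broken by lexicographically smallest id).
#'
#' @param g a [genotype_matrix()] with at least two samples
#' @param t a [qc_thresholds()]
#' @return list with `retained`, `removed` sample ids and the `ibs` matrix
#' @export
duplicate_prune <- function(g, t = qc_thresholds()) {
  stopifnot(length(g$samples) >= 2)
  ibs <- ibs_matrix(g)
  res <- prune_by_pairs(g, ibs, t$ibs_dup)
  c(res, list(ibs = ibs))
}

#' Relatedness pruning by robust kinship
#'
#' Pairs with kinship above `kinship_max` (default 0.0441, the third-degree
#' cutoff) form relative clusters; one highest-call-rate member survives per
#' cluster.
#'
#' @param g a [genotype_matrix()] with at least two samples
#' @param t a [qc_thresholds()]
#' @return list with `retained`, `removed` sample ids and the `kinship`
#'   matrix
#' @export
kinship_prune <- function(g, t = qc_thresholds()) {
  stopifnot(length(g$samples) >= 2)
  phi <- kinship_matrix(g)
  res <- prune_by_pairs(g, phi, t$kinship_max)
  c(res, list(kinship = phi))
}

#' Ancestry-proportion filter
#'
#' Removes samples whose African ancestry fraction is strictly below the
#' threshold (a sample at exactly the threshold is retained).
#'
#' @param proportions data.frame with a `sample` column and one column per
#'   ancestral population, fractions summing to 1 (within 1e-6) per sample;
#'   an `African` column must be present
#' @param t a [qc_thresholds()]
#' @return list with `retained` and `removed` sample ids
#' @export
ancestry_filter <- function(proportions, t = qc_thresholds()) {
  stopifnot(is.data.frame(proportions), "sample" %in% names(proportions))
  if (!"African" %in% names(proportions)) {
    stop("ancestry table must contain an 'African' component")
  }
  fr <- proportions[, setdiff(names(proportions), "sample"), drop = FALSE]
  sums <- rowSums(fr)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("ancestry fractions must sum to 1 (within 1e-6) for every sample")
  }
  keep <- proportions$African >= t$african_ancestry_min
  list(retained = proportions$sample[keep],
       removed = proportions$sample[!keep])
}

#' Serialize a QC report to JSON
#' @param report a report list (e.g. from [snp_qc()] or [run_pipeline()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
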