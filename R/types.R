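#' Domain containers for genotype and imputation data
#'
#' `genotype_matrix` holds discrete genotypes as ALT-allele copy counts
#' (0/1/2, `NA` for missing) for a set of biallelic SNVs; `posterior_matrix`
#' holds per-genotype probability triplets from an imputation run. Both are
#' site-major: variants in rows, samples in columns. Genotypes always count
#' ALT-allele copies; "minor allele" orientation is resolved at the point of
#' use (MAF computation), never by re-coding stored data.
#'
#' @name imputeval-types
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Build and validate a variant table
#'
#' @param chrom chromosome labels
#' @param pos 1-based positions
#' @param vid variant identifiers (unique)
#' @param ref,alt single-base reference / alternate alleles; indels and
#'   multiallelic records are rejected, matching a SNV-only analysis
#' @return data.frame with columns chrom, pos, vid, ref, alt
#' @export
variant_table <- function(chrom, pos, vid, ref, alt) {
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  vid = as.character(vid), ref = toupper(as.character(ref)),
                  alt = toupper(as.character(alt)), stringsAsFactors = FALSE)
  bad <- !(v$ref %in% VALID_BASES) | !(v$alt %in% VALID_BASES) | v$ref == v$alt
  if (any(bad)) {
    stop("invalid variant(s) (must be biallelic SNVs, ref != alt): ",
         paste(utils::head(v$vid[bad], 5), collapse = ", "))
  }
  key <- paste(v$chrom, v$pos, v$ref, v$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) in variant table")
  if (anyDuplicated(v$vid)) stop("duplicate variant identifiers")
  v
}

#' Construct a genotype matrix
#'
#' @param variants variant table (see [variant_table()])
#' @param samples character vector of sample identifiers
#' @param calls integer matrix (variants x samples) of ALT-allele copy
#'   counts in \{0, 1, 2\}; `NA` encodes a missing call
#' @return object of class `genotype_matrix`
#' @export
genotype_matrix <- function(variants, samples, calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.character(samples)
  stopifnot(nrow(calls) == nrow(variants), ncol(calls) == length(samples))
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (length(calls) && !all(is.na(calls))) {
    rng <- range(calls, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > 2L) stop("genotype calls must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(variants$vid, samples)
  structure(list(variants = variants, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples (%.1f%% called)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(!is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-variant call rate (fraction of non-missing genotypes)
#' @param g a `genotype_matrix`
#' @return numeric vector, one value per variant
#' @export
call_rate <- function(g) rowMeans(!is.na(g$calls))

#' Per-variant minor allele frequency from discrete calls
#'
#' Computed on non-missing calls; the minor allele is whichever of REF/ALT is
#' rarer at this use-site, so the result is always in [0, 0.5].
#' @param g a `genotype_matrix`
#' @return numeric vector (NA for variants with no calls)
#' @export
maf_from_calls <- function(g) {
  p <- rowMeans(g$calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Construct a posterior-probability matrix
#'
#' Triplets are renormalized to sum to one; sums must already lie within
#' `tol` of 1 (loaders enforce a looser malformed-record band before calling
#' this).
#'
#' @param variants variant table
#' @param samples sample identifiers
#' @param p0,p1,p2 matrices (variants x samples) of probabilities for
#'   genotypes 0, 1 and 2 ALT copies
#' @param dosage_derived flag set when the triplets were expanded from
#'   dosages (information was lost; see [read_imputed()])
#' @param tol allowed deviation of each triplet sum from 1 before
#'   renormalization
#' @return object of class `posterior_matrix`
#' @export
posterior_matrix <- function(variants, samples, p0, p1, p2,
                             dosage_derived = FALSE, tol = 1e-4) {
  p0 <- as.matrix(p0); p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  samples <- as.character(samples)
  stopifnot(all(dim(p0) == dim(p1)), all(dim(p0) == dim(p2)),
            nrow(p0) == nrow(variants), ncol(p0) == length(samples))
  if (min(p0, p1, p2) < 0) stop("posterior probabilities must be non-negative")
  s <- p0 + p1 + p2
  if (any(abs(s - 1) > tol)) {
    stop(sprintf("posterior triplet sums deviate from 1 by more than %g", tol))
  }
  p0 <- p0 / s; p1 <- p1 / s; p2 <- p2 / s
  dimnames(p0) <- dimnames(p1) <- dimnames(p2) <- list(variants$vid, samples)
  structure(list(variants = variants, samples = samples,
                 p0 = p0, p1 = p1, p2 = p2,
                 dosage_derived = isTRUE(dosage_derived)),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("posterior_matrix: %d variants x %d samples%s\n",
              nrow(x$p0), ncol(x$p0),
              if (x$dosage_derived) " (dosage-derived)" else ""))
  invisible(x)
}

#' @export
dim.posterior_matrix <- function(x) dim(x$p0)

#' Expected ALT-allele dosages from a posterior matrix
#'
#' dosage = p1 + 2 p2, a value in [0, 2] per genotype.
#' @param p a `posterior_matrix`
#' @return numeric matrix (variants x samples)
#' @export
dosages <- function(p) {
  d <- p$p1 + 2 * p$p2
  pmin(pmax(d, 0), 2)   # argument order keeps the matrix attributes
}
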