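#' Read true genotypes from VCF or site-major matrix text
#'
#' Supported formats:
#' \describe{
#'   \item{`vcf`}{VCF 4.x with a GT field. Multiallelic sites and indels are
#'     skipped (counts attached as attributes `n_skipped_multiallelic`,
#'     `n_skipped_indel`); half-missing diploid calls (e.g. `./1`) become
#'     missing.}
#'   \item{`matrix-text`}{whitespace-delimited text, one row per variant:
#'     `chrom pos vid ref alt` followed by one 0/1/2 call per sample; header
#'     line carries the sample identifiers. `./.`, `.` and `NA` encode
#'     missing calls.}
#' }
#'
#' @param path input file
#' @param format one of `"vcf"`, `"matrix-text"`
#' @return a [genotype_matrix()] with skip-count attributes
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  switch(format,
         "vcf" = read_genotypes_vcf(path),
         "matrix-text" = read_genotypes_matrix(path))
}

# Map diploid GT strings ("0/1", "1|1", "./1", ...) to ALT copy counts.
gt_to_calls <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  }, integer(1))
  m <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

vcf_snv_mask <- function(fix) {
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snv <- !multi & fix[, "REF"] %in% VALID_BASES & alt %in% VALID_BASES
  list(keep = snv & !multi, n_multi = sum(multi), n_indel = sum(!multi & !snv))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) stop("empty dataset: no records in ", path)
  msk <- vcf_snv_mask(fix)
  if (!any(msk$keep)) stop("empty dataset: no biallelic SNVs in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  fix <- fix[msk$keep, , drop = FALSE]
  gt <- gt[msk$keep, , drop = FALSE]
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vid) | vid == "."]
  v <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]), vid,
                     fix[, "REF"], fix[, "ALT"])
  g <- genotype_matrix(v, colnames(gt), gt_to_calls(gt))
  attr(g, "n_skipped_multiallelic") <- msk$n_multi
  attr(g, "n_skipped_indel") <- msk$n_indel
  g
}

read_genotypes_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("empty dataset: ", path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (identical(tolower(header[1]), "chrom")) header <- header[-(1:5)]
  samples <- header
  body <- strsplit(trimws(lines[-1]), "[ \t]+")
  ncols <- 5 + length(samples)
  if (any(lengths(body) != ncols)) stop("malformed matrix-text record in ", path)
  m <- do.call(rbind, body)
  v <- variant_table(m[, 1], as.integer(m[, 2]), m[, 3], m[, 4], m[, 5])
  raw <- m[, -(1:5), drop = FALSE]
  raw[raw %in% c("./.", ".", "NA")] <- NA
  calls <- matrix(as.integer(raw), nrow = nrow(m))
  genotype_matrix(v, samples, calls)
}

#' Write genotypes to a supported format
#'
#' @param g a [genotype_matrix()]
#' @param path output file
#' @param format `"matrix-text"` or `"vcf"` (VCF 4.2, GT only)
#' @return `path`, invisibly
#' @export
write_genotypes <- function(g, path, format = c("matrix-text", "vcf")) {
  format <- match.arg(format)
  v <- g$variants
  if (format == "matrix-text") {
    body <- g$calls
    mode(body) <- "character"
    body[is.na(body)] <- "./."
    lines <- c(paste(c("chrom", "pos", "vid", "ref", "alt", g$samples),
                     collapse = "\t"),
               paste(v$chrom, v$pos, v$vid, v$ref, v$alt,
                     apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  } else {
    gtmap <- c("0/0", "0/1", "1/1")
    body <- matrix(gtmap[g$calls + 1L], nrow = nrow(g$calls))
    body[is.na(body)] <- "./."
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t"),
               paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", ".", ".", "GT",
                     apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read imputed genotype probabilities or dosages
#'
#' Supported formats:
#' \describe{
#'   \item{`gen-triplet`}{IMPUTE2-style GEN text: `chrom vid pos ref alt`
#'     then three probabilities per sample. Triplets are renormalized to sum
#'     to 1 (sub-unit sums carry unassigned probability mass in this
#'     format); a pre-normalization sum above 1.05 or not positive is a
#'     malformed record.}
#'   \item{`dosage`}{MaCH-style sample-major dosage text (`id word d1 d2
#'     ...`). Variant metadata is not present in such files; supply
#'     `variants` (an mlinfo-style table with columns vid, ref, alt and
#'     optionally chrom, pos) or placeholder records are synthesized.
#'     Dosages expand to a degenerate posterior on the two adjacent integer
#'     genotypes (mass `1 - frac` on `floor(d)`, `frac` on `floor(d) + 1`),
#'     which preserves the dosage but not the full posterior; the result is
#'     flagged `dosage_derived`.}
#'   \item{`vcf-gp`}{VCF with a GP (genotype probability) field, or a DS
#'     (dosage) field as fallback, handled as above.}
#' }
#'
#' @param path input file
#' @param format one of `"gen-triplet"`, `"dosage"`, `"vcf-gp"`
#' @param samples sample identifiers for headerless formats (default
#'   `S1..Sn`)
#' @param variants optional variant table for the `dosage` format
#' @return a [posterior_matrix()]
#' @export
read_imputed <- function(path, format = c("gen-triplet", "dosage", "vcf-gp"),
                         samples = NULL, variants = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read imputed file: ", path)
  switch(format,
         "gen-triplet" = read_imputed_gen(path, samples),
         "dosage" = read_imputed_dosage(path, variants),
         "vcf-gp" = read_imputed_vcf(path))
}

triplets_to_posterior <- function(v, samples, tri) {
  # tri: variants x (3 * samples) numeric matrix of (p0, p1, p2) triplets
  idx <- seq_len(ncol(tri) / 3)
  p0 <- tri[, 3 * idx - 2, drop = FALSE]
  p1 <- tri[, 3 * idx - 1, drop = FALSE]
  p2 <- tri[, 3 * idx, drop = FALSE]
  s <- p0 + p1 + p2
  # GEN-style triplets legitimately sum below 1 (unassigned probability
  # mass) and are renormalized; sums above 1.05 or non-positive are corrupt
  if (any(s <= 0 | s > 1.05)) {
    stop("malformed record: posterior triplet sum non-positive or above 1.05")
  }
  posterior_matrix(v, samples, p0 / s, p1 / s, p2 / s)
}

read_imputed_gen <- function(path, samples) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty dataset: ", path)
  body <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(body)
  if (length(unique(nf)) != 1 || (nf[1] - 5) %% 3 != 0) {
    stop("malformed record: GEN triplet count not divisible by 3")
  }
  m <- do.call(rbind, body)
  v <- variant_table(m[, 1], as.integer(m[, 3]), m[, 2], m[, 4], m[, 5])
  tri <- matrix(as.numeric(m[, -(1:5)]), nrow = nrow(m))
  ns <- ncol(tri) / 3
  samples <- samples %||% paste0("S", seq_len(ns))
  stopifnot(length(samples) == ns)
  triplets_to_posterior(v, samples, tri)
}

#' Expand dosages to an adjacent-integer posterior
#' @noRd
dosage_to_triplet <- function(d) {
  stopifnot(all(d >= 0 & d <= 2))
  g <- pmin(floor(d), 1)          # lower adjacent genotype (0 or 1)
  frac <- d - floor(d)
  frac[d == 2] <- 1               # d = 2 sits on the upper boundary
  p_low <- 1 - frac
  p0 <- ifelse(g == 0, p_low, 0)
  p1 <- ifelse(g == 0, frac, p_low)
  p2 <- ifelse(g == 1, frac, 0)
  list(p0 = p0, p1 = p1, p2 = p2)
}

read_imputed_dosage <- function(path, variants) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty dataset: ", path)
  body <- strsplit(trimws(lines), "[ \t]+")
  if (length(unique(lengths(body))) != 1) stop("malformed record: ragged dosage file")
  m <- do.call(rbind, body)
  ids <- sub("^.*->", "", m[, 1])
  d <- matrix(as.numeric(m[, -(1:2), drop = FALSE]), nrow = nrow(m))
  d <- t(d)                       # to site-major
  nv <- nrow(d)
  if (is.null(variants)) {
    variants <- variant_table(rep("1", nv), seq_len(nv), paste0("V", seq_len(nv)),
                              rep("A", nv), rep("G", nv))
  }
  stopifnot(nrow(variants) == nv)
  tr <- dosage_to_triplet(d)
  pm <- posterior_matrix(variants, ids, tr$p0, tr$p1, tr$p2,
                         dosage_derived = TRUE)
  pm
}

read_imputed_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) stop("empty dataset: no records in ", path)
  msk <- vcf_snv_mask(fix)
  if (!any(msk$keep)) stop("empty dataset: no biallelic SNVs in ", path)
  fmt <- vcf@gt[1, "FORMAT"]
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vid) | vid == "."]
  v <- variant_table(fix[msk$keep, "CHROM"], as.integer(fix[msk$keep, "POS"]),
                     vid[msk$keep], fix[msk$keep, "REF"], fix[msk$keep, "ALT"])
  if (grepl("(^|:)GP(:|$)", fmt)) {
    gp <- vcfR::extract.gt(vcf, element = "GP")[msk$keep, , drop = FALSE]
    parts <- strsplit(as.vector(gp), ",", fixed = TRUE)
    num <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
    nr <- nrow(gp)
    shape <- function(k) matrix(num[, k], nrow = nr)
    tri <- matrix(0, nr, 3 * ncol(gp))
    tri[, seq(1, ncol(tri), 3)] <- shape(1)
    tri[, seq(2, ncol(tri), 3)] <- shape(2)
    tri[, seq(3, ncol(tri), 3)] <- shape(3)
    triplets_to_posterior(v, colnames(gp), tri)
  } else if (grepl("(^|:)DS(:|$)", fmt)) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)[msk$keep, , drop = FALSE]
    tr <- dosage_to_triplet(ds)
    posterior_matrix(v, colnames(ds), tr$p0, tr$p1, tr$p2, dosage_derived = TRUE)
  } else {
    stop("VCF has neither GP nor DS field: ", path)
  }
}

#' Write imputed posteriors to a supported format
#'
#' @param p a [posterior_matrix()]
#' @param path output file
#' @param format `"gen-triplet"`, `"dosage"` (writes expected dosages;
#'   posterior detail beyond the dosage is lost) or `"vcf-gp"`
#' @return `path`, invisibly
#' @export
write_imputed <- function(p, path, format = c("gen-triplet", "dosage", "vcf-gp")) {
  format <- match.arg(format)
  v <- p$variants
  fmtnum <- function(x) formatC(x, digits = 9, format = "g")
  if (format == "gen-triplet") {
    nv <- nrow(v)
    tri <- matrix("", nv, 3 * length(p$samples))
    tri[, seq(1, ncol(tri), 3)] <- fmtnum(p$p0)
    tri[, seq(2, ncol(tri), 3)] <- fmtnum(p$p1)
    tri[, seq(3, ncol(tri), 3)] <- fmtnum(p$p2)
    lines <- paste(v$chrom, v$vid, v$pos, v$ref, v$alt,
                   apply(tri, 1, paste, collapse = " "))
  } else if (format == "dosage") {
    d <- t(dosages(p))
    lines <- paste(paste0(p$samples, "->", p$samples), "ML_DOSE",
                   apply(d, 1, function(r) paste(fmtnum(r), collapse = "\t")),
                   sep = "\t")
  } else {
    gp <- matrix(paste(fmtnum(p$p0), fmtnum(p$p1), fmtnum(p$p2), sep = ","),
                 nrow = nrow(v))
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", p$samples), collapse = "\t"),
               paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", ".", ".", "GP",
                     apply(gp, 1, paste, collapse = "\t"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_strand_ambiguous <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Harmonize imputed variants against the truth set
#'
#' Variants are matched on (chrom, pos). If the imputed REF/ALT labels are
#' swapped relative to the truth, triplets are reversed (p0 <-> p2); if they
#' match only after strand complement, the complement is applied and then
#' swap-checked. Strand-ambiguous pairs (A/T, C/G) are matched by label only
#' and excluded when labels disagree (no frequency-based rescue). Unmatched
#' variants are dropped. The operation is idempotent: output variants carry
#' the truth's allele labels.
#'
#' @param imputed a [posterior_matrix()]
#' @param truth a [genotype_matrix()]
#' @return posterior matrix restricted to harmonized shared variants, with
#'   attribute `align_counts` (kept, swapped, complemented,
#'   ambiguous_excluded, mismatch_excluded, unmatched)
#' @export
align_alleles <- function(imputed, truth) {
  if (nrow(imputed$p0) == 0 || nrow(truth$calls) == 0) {
    stop("align_alleles requires non-empty inputs")
  }
  iv <- imputed$variants
  tv <- truth$variants
  key_i <- paste(iv$chrom, iv$pos)
  key_t <- paste(tv$chrom, tv$pos)
  m <- match(key_i, key_t)

  n <- nrow(iv)
  action <- rep("unmatched", n)        # keep | swap | drop-ambiguous | drop-mismatch
  hit <- !is.na(m)
  if (any(hit)) {
    tr <- tv$ref[m[hit]]; ta <- tv$alt[m[hit]]
    ir <- iv$ref[hit];    ia <- iv$alt[hit]
    icr <- unname(COMPLEMENT[ir]); ica <- unname(COMPLEMENT[ia])
    amb <- is_strand_ambiguous(tr, ta)
    act <- ifelse(ir == tr & ia == ta, "keep",
           ifelse(amb, "drop-ambiguous",
           ifelse(ir == ta & ia == tr, "swap",
           ifelse(icr == tr & ica == ta, "keep",
           ifelse(icr == ta & ica == tr, "swap", "drop-mismatch")))))
    # ambiguous sites that agree exactly were caught by the first branch
    action[hit] <- act
  }
  counts <- c(kept = sum(action %in% c("keep", "swap")),
              swapped = sum(action == "swap"),
              ambiguous_excluded = sum(action == "drop-ambiguous"),
              mismatch_excluded = sum(action == "drop-mismatch"),
              unmatched = sum(action == "unmatched"))
  sel <- which(action %in% c("keep", "swap"))
  if (!length(sel)) stop("empty dataset: no variants survive allele alignment")
  swap <- action[sel] == "swap"
  p0 <- imputed$p0[sel, , drop = FALSE]
  p1 <- imputed$p1[sel, , drop = FALSE]
  p2 <- imputed$p2[sel, , drop = FALSE]
  p0s <- p0; p0[swap, ] <- p2[swap, ]; p2[swap, ] <- p0s[swap, ]
  vkeep <- tv[m[sel], , drop = FALSE]  # truth labels after harmonization
  rownames(vkeep) <- NULL
  out <- posterior_matrix(vkeep, imputed$samples, p0, p1, p2,
                          dosage_derived = imputed$dosage_derived)
  attr(out, "align_counts") <- counts
  out
}
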