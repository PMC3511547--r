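# Independent oracles and fixture builders used across the suite.

# Cohen's kappa on a 3x3 table, coded directly from the kappa formula
# (independent of the package's iqs()).
kappa_oracle <- function(tab) {
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2] + tab[3, 3]) / n
  marg_r <- rowSums(tab) / n
  marg_c <- colSums(tab) / n
  pe <- marg_r[1] * marg_c[1] + marg_r[2] * marg_c[2] + marg_r[3] * marg_c[3]
  if (pe == 1) return(NA_real_)
  unname((po - pe) / (1 - pe))
}

# Exact HWE p-value by full enumeration: probability of each heterozygote
# count proportional to the number of genotype configurations
# n! / (n0! h! n2!) * 2^h, normalized numerically (no closed-form allele
# normalization, unlike the implementation).
hwe_enum_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1
  na <- 2 * n2 + n1
  if (nA == 0 || na == 0) return(1.0)
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  w <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- (na - h) / 2
    choose(n, a) * choose(n - a, h) * 2^h
  }, numeric(1))
  pr <- w / sum(w)
  pobs <- pr[hets == n1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

random_table3 <- function() {
  matrix(sample(0:50, 9, replace = TRUE), 3, 3)
}

# Minimal genotype_matrix from a calls matrix (variants auto-labelled).
make_gm <- function(calls, samples = NULL, chrom = "1") {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  samples <- samples %||% paste0("s", seq_len(ncol(calls)))
  v <- variant_table(rep(chrom, n), seq_len(n), paste0("v", seq_len(n)),
                     rep("A", n), rep("G", n))
  genotype_matrix(v, samples, calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# HWE genotype draws at ALT frequency p.
hwe_draw <- function(n, p) rbinom(n, 2L, p)

# HWE genotype-class frequencies (g = 0, 1, 2 ALT copies) at ALT freq p.
hwe_freqs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# Small per-population allele-frequency table fixture covering the
# fourteen reference populations for a handful of variants.
toy_af <- function(vids, values) {
  pops <- kg_populations()$code
  af <- matrix(values, nrow = length(vids), ncol = length(pops),
               dimnames = list(vids, pops))
  af
}
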