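#' Synthetic study generator
#'
#' Generates data with the statistical structure the evaluation assumes,
#' without any external downloads: Hardy-Weinberg genotypes across a MAF
#' spectrum, multi-population allele-frequency divergence under the
#' Balding-Nichols model (so some SNPs are monomorphic in a close panel but
#' polymorphic in a diverse one), two-way admixed ancestry, and a
#' parameterized imputation channel emitting posterior probabilities with
#' tunable, MAF- and panel-dependent error. The channel is deliberately a
#' two-parameter (miscall rate, calibration) model rather than a
#' haplotype-copying imputer: every performance metric has a closed-form
#' expectation under it, which is what makes the evaluation testable.
#'
#' @name synthetic
NULL

#' Imputation-channel parameters
#'
#' Per genotype, with probability `e'` the reported genotype is a fresh
#' Hardy-Weinberg draw from the SNP's prior frequency instead of the truth;
#' the emitted posterior is `q * point-mass(reported) + (1 - q) * HWE
#' prior`. `e' = base_error + panel_penalty` (for SNPs monomorphic in the
#' designated close subpanel) `+ maf_penalty` (for SNPs with prior MAF <=
#' 2%), clipped to [0, 1]. For the penalized population-specific SNPs the
#' calibration is additionally flattened to `q * (1 - calibration_penalty)`:
#' an imputer with no information about a SNP in the relevant ancestries
#' emits diffuse posteriors, and it is the flattening — not the miscall
#' rate — that drives their variance-ratio r2hat down.
#'
#' @param base_error probability a reported genotype is a prior draw
#' @param calibration posterior sharpness q in [0, 1]
#' @param panel_penalty additive error for SNPs monomorphic in the close
#'   subpanel
#' @param maf_penalty additive error for SNPs with prior MAF <= 0.02
#' @param calibration_penalty multiplicative flattening of q for the
#'   panel-penalized SNPs
#' @return list of class `channel_params`
#' @export
channel_params <- function(base_error = 0.05, calibration = 0.9,
                           panel_penalty = 0.15, maf_penalty = 0.2,
                           calibration_penalty = 0.45) {
  p <- list(base_error = base_error, calibration = calibration,
            panel_penalty = panel_penalty, maf_penalty = maf_penalty,
            calibration_penalty = calibration_penalty)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  structure(p, class = "channel_params")
}

#' Synthetic study configuration
#'
#' Defaults define the study conditions the whole pipeline is exercised
#' under: 3000 SNPs of which two sixths are planted population-specific
#' (500 monomorphic in the close panel's populations, 500 monomorphic in
#' everything but the remaining diverse populations), a rare-weighted
#' ancestral MAF spectrum (log-uniform on [0.001, 0.5], putting ~48% of
#' SNPs at MAF <= 2%), Balding-Nichols divergence Fst = 0.02, 200 study
#' samples admixed Beta(8, 2) between an African and a European ancestral
#' population (mean 80% African ancestry), 2% masking with 10 repetitions.
#'
#' @param n_snps total number of SNPs (shared + planted)
#' @param n_samples number of study samples
#' @param maf_law list(type = "spectrum" | "uniform", lo, hi); `"spectrum"`
#'   is log-uniform (density proportional to 1/p), weighted toward rare
#' @param fst Balding-Nichols divergence parameter in (0, 1)
#' @param populations data.frame(code, count, group) of reference
#'   populations (default [kg_populations()])
#' @param ancestry_pops named pair: which population codes supply the
#'   African and European ancestral frequencies of the study sample
#' @param admixture_law Beta shape parameters of the per-sample African
#'   ancestry fraction
#' @param planted list of planted SNP groups, each
#'   list(fraction, zero_groups, maf = c(lo, hi)): `fraction` of `n_snps`
#'   forced to frequency 0 in the populations whose `group` is in
#'   `zero_groups`, with ancestral MAF drawn uniformly from `maf`
#' @param channel a [channel_params()]
#' @param mask list(fraction, reps) for the masking harness
#' @param missing_rate per-call missingness injected into the truth
#' @param seed root RNG seed; per-stage child seeds are derived from it
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_snps = 3000, n_samples = 200,
                       maf_law = list(type = "spectrum", lo = 0.001, hi = 0.5),
                       fst = 0.02,
                       populations = kg_populations(),
                       ancestry_pops = c(African = "YRI", European = "CEU"),
                       admixture_law = c(8, 2),
                       planted = list(
                         list(fraction = 1 / 6, zero_groups = "close",
                              maf = c(0.001, 0.015)),
                         list(fraction = 1 / 6,
                              zero_groups = c("close", "afr_eur"),
                              maf = c(0.001, 0.015))),
                       channel = channel_params(),
                       mask = list(fraction = 0.02, reps = 10),
                       missing_rate = 0,
                       seed = 1) {
  stopifnot(fst > 0, fst < 1,
            maf_law$lo > 0, maf_law$hi <= 0.5,
            maf_law$type %in% c("spectrum", "uniform"),
            all(ancestry_pops %in% populations$code),
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_snps = n_snps, n_samples = n_samples, maf_law = maf_law,
                 fst = fst, populations = populations,
                 ancestry_pops = ancestry_pops,
                 admixture_law = admixture_law, planted = planted,
                 channel = channel, mask = mask,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

draw_maf <- function(law, n) {
  switch(law$type,
         uniform = stats::runif(n, law$lo, law$hi),
         spectrum = exp(stats::runif(n, log(law$lo), log(law$hi))))
}

#' Simulate per-population allele frequencies
#'
#' Each SNP gets an ancestral frequency from the configured MAF law; each
#' population's frequency is a Balding-Nichols draw
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` around it. Planted groups are then
#' forced to frequency exactly 0 in their designated populations (exactly
#' `round(fraction * n_snps)` SNPs per group, taken from the tail of the
#' SNP index so the assignment is deterministic).
#'
#' @param cfg a [sim_config()]
#' @param seed RNG seed (default: derived from `cfg$seed`)
#' @return list with `af` (SNP x population frequency matrix), `anc`
#'   (ancestral frequencies), `vids`, and `planted` (list of vid vectors,
#'   one per planted group; `planted_all` is their union)
#' @export
simulate_population_freqs <- function(cfg, seed = NULL) {
  seed <- seed %||% derive_seeds(cfg$seed, 1)[1]
  pops <- cfg$populations
  n <- cfg$n_snps
  vids <- sprintf("snp%05d", seq_len(n))
  k <- vapply(cfg$planted, function(g) round_half_away(g$fraction * n), numeric(1))
  stopifnot(sum(k) < n)
  # planted groups occupy the tail of the index, shared SNPs the head
  bounds <- n - rev(cumsum(rev(k)))
  planted_idx <- lapply(seq_along(k), function(i) {
    seq.int(bounds[i] + 1L, bounds[i] + k[i])
  })
  with_seed(seed, {
    anc <- draw_maf(cfg$maf_law, n)
    for (i in seq_along(cfg$planted)) {
      g <- cfg$planted[[i]]
      anc[planted_idx[[i]]] <- stats::runif(k[i], g$maf[1], g$maf[2])
    }
    f <- cfg$fst
    af <- vapply(pops$code, function(code) {
      stats::rbeta(n, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
    }, numeric(n))
    rownames(af) <- vids
    for (i in seq_along(cfg$planted)) {
      zero_pops <- pops$code[pops$group %in% cfg$planted[[i]]$zero_groups]
      af[planted_idx[[i]], zero_pops] <- 0
    }
    list(af = af, anc = anc, vids = vids,
         planted = lapply(planted_idx, function(ix) vids[ix]),
         planted_all = vids[unlist(planted_idx)])
  })
}

#' Simulate study genotypes under admixture
#'
#' Each study sample draws an African ancestry fraction theta from the
#' configured Beta law (theta = 1 reduces to an unadmixed draw); each
#' allele copy independently comes from the African ancestral population
#' with probability theta, else the European one, then is a Bernoulli draw
#' at that population's frequency — equivalently genotype ~ Binomial(2,
#' theta p_Afr + (1 - theta) p_Eur), Hardy-Weinberg within each sample's
#' own mixture frequency. Optional uniform missingness is injected.
#'
#' @param freqs a [simulate_population_freqs()] result
#' @param cfg a [sim_config()]
#' @param ancestry optional numeric vector of per-sample African fractions
#'   (default: drawn from `cfg$admixture_law`)
#' @param seed RNG seed (default: derived from `cfg$seed`)
#' @return a [genotype_matrix()] with attribute `sample_info`
#'   (data.frame sample, african, european)
#' @export
simulate_genotypes <- function(freqs, cfg, ancestry = NULL, seed = NULL) {
  seed <- seed %||% derive_seeds(cfg$seed, 2)[2]
  n <- cfg$n_snps
  s <- cfg$n_samples
  p_afr <- freqs$af[, cfg$ancestry_pops[["African"]]]
  p_eur <- freqs$af[, cfg$ancestry_pops[["European"]]]
  with_seed(seed, {
    theta <- ancestry %||%
      stats::rbeta(s, cfg$admixture_law[1], cfg$admixture_law[2])
    stopifnot(length(theta) == s, all(theta >= 0 & theta <= 1))
    pmix <- outer(p_afr, theta) + outer(p_eur, 1 - theta)
    calls <- matrix(stats::rbinom(n * s, 2L, pmix), nrow = n)
    if (cfg$missing_rate > 0) {
      calls[stats::runif(n * s) < cfg$missing_rate] <- NA_integer_
    }
    samples <- sprintf("ind%04d", seq_len(s))
    v <- variant_table(rep("22", n), seq_len(n) * 1000L, freqs$vids,
                       rep("A", n), rep("G", n))
    g <- genotype_matrix(v, samples, calls)
    attr(g, "sample_info") <- data.frame(sample = samples, african = theta,
                                         european = 1 - theta)
    g
  })
}

#' The synthetic imputation channel
#'
#' Per genotype: with probability `e'` (base error plus applicable
#' penalties, clipped to [0, 1]) the reported genotype is a fresh
#' Hardy-Weinberg draw from the SNP's prior frequency, otherwise it is the
#' truth (missing truth is always a prior draw). The emitted posterior is
#' `q_eff * point-mass(reported) + (1 - q_eff) * HWE prior triplet`, where
#' `q_eff` is the calibration, flattened for planted SNPs (see
#' [channel_params()]). With `e = 0, q = 1` the posterior is the exact
#' truth; with `e = 1, q = 1` it is independent of the truth.
#'
#' @param truth a [genotype_matrix()] (the channel imputes each of its
#'   variants independently)
#' @param prior named per-variant ALT prior frequency (names = vids,
#'   covering the truth variants); typically a panel's pooled frequency
#' @param params a [channel_params()]
#' @param planted_vids variant ids subject to the panel penalty
#'   (monomorphic in the designated close subpanel)
#' @param seed RNG seed
#' @return a [posterior_matrix()] over the truth's variants
#' @export
imputation_channel <- function(truth, prior, params = channel_params(),
                               planted_vids = character(), seed = 1) {
  v <- truth$variants
  p <- prior[v$vid]
  stopifnot(!anyNA(p), all(p >= 0 & p <= 1))
  n <- nrow(v)
  s <- length(truth$samples)
  planted <- v$vid %in% planted_vids
  maf <- pmin(p, 1 - p)
  e <- clip01(params$base_error + params$panel_penalty * planted +
                params$maf_penalty * (maf <= 0.02))
  q <- params$calibration * (1 - params$calibration_penalty * planted)
  with_seed(seed, {
    err <- matrix(stats::runif(n * s) < e, nrow = n)       # recycles e by row
    draw <- matrix(stats::rbinom(n * s, 2L, p), nrow = n)  # recycles p by row
    reported <- truth$calls
    take <- err | is.na(reported)
    reported[take] <- draw[take]
    prior0 <- (1 - p)^2
    prior1 <- 2 * p * (1 - p)
    prior2 <- p^2
    p0 <- q * (reported == 0L) + (1 - q) * prior0
    p1 <- q * (reported == 1L) + (1 - q) * prior1
    p2 <- q * (reported == 2L) + (1 - q) * prior2
    posterior_matrix(v, truth$samples, p0, p1, p2)
  })
}

subset_genotypes <- function(g, vids) {
  ix <- match(vids, g$variants$vid)
  stopifnot(!anyNA(ix))
  genotype_matrix(g$variants[ix, , drop = FALSE], g$samples,
                  g$calls[ix, , drop = FALSE])
}

subset_posterior <- function(p, vids) {
  ix <- match(vids, p$variants$vid)
  stopifnot(!anyNA(ix))
  posterior_matrix(p$variants[ix, , drop = FALSE], p$samples,
                   p$p0[ix, , drop = FALSE], p$p1[ix, , drop = FALSE],
                   p$p2[ix, , drop = FALSE],
                   dosage_derived = p$dosage_derived)
}

#' Full synthetic three-panel study
#'
#' Builds the nested close / African+European / cosmopolitan panels from
#' the simulated population frequencies, simulates admixed study truth over
#' every SNP, runs one imputation-channel realization over the union SNP
#' set (each panel's result is its polymorphic subset, so panel
#' comparisons on shared SNPs are exact, not resampled), generates the
#' masking repetitions over the chip SNPs (the non-planted, genotyped
#' subset) with a fresh channel realization per repetition, and assembles
#' per-SNP metrics and summaries per panel. The channel's prior is the
#' cosmopolitan panel's pooled frequency throughout.
#'
#' The planted population-specific SNPs only enter the diverse panels'
#' imputed sets and carry the panel and MAF penalties, so across panels the
#' fraction of low-frequency (MAF <= 2%) imputed SNPs rises and the overall
#' mean r2hat falls, while the MAF > 2% stratum is untouched — the
#' qualitative pattern a diverse reference panel produces in an admixed
#' study population.
#'
#' @param cfg a [sim_config()]
#' @return list of class `imputation_scenario` with fields config, freqs,
#'   truth, panels, prior, posterior, chip_vids, plans, rep_posteriors,
#'   metrics (per panel), summaries (per panel), planted_vids
#' @export
scenario_three_panels <- function(cfg = sim_config()) {
  reps <- cfg$mask$reps
  seeds <- derive_seeds(cfg$seed, 4 + reps)
  fr <- simulate_population_freqs(cfg, seed = seeds[1])
  truth <- simulate_genotypes(fr, cfg, seed = seeds[2])

  panels <- list(
    close = compose_panel("close", panel_members("close"), fr$af),
    afr_eur = compose_panel("afr_eur", panel_members("afr_eur"), fr$af),
    all = compose_panel("all", panel_members("all"), fr$af)
  )
  prior <- panels$all$pooled
  poly_vids <- lapply(panels, function(pn) setdiff(fr$vids, monomorphic_set(pn)))

  post <- imputation_channel(truth, prior, cfg$channel,
                             planted_vids = fr$planted_all, seed = seeds[3])

  # chip = genotyped shared SNPs; anything monomorphic in the close panel
  # would not segregate in the study and never survive chip QC
  chip_vids <- setdiff(setdiff(fr$vids, fr$planted_all),
                       monomorphic_set(panels$close))
  plans <- build_mask_plans(chip_vids, cfg$mask$fraction, reps,
                            base_seed = seeds[4])
  rep_posteriors <- lapply(seq_len(reps), function(r) {
    mv <- plans[[r]]$masked_vids
    imputation_channel(subset_genotypes(truth, mv), prior, cfg$channel,
                       planted_vids = fr$planted_all, seed = seeds[4 + r])
  })

  # metrics: one full-imputation table over the union set (dosage MAF),
  # shared across panels by subsetting; plus per-rep masked rows (truth MAF)
  union_tab <- snp_metrics(post)
  masked_tab <- do.call(rbind, lapply(seq_len(reps), function(r) {
    snp_metrics(rep_posteriors[[r]], truth = truth,
                vids = plans[[r]]$masked_vids, rep = r)
  }))
  metrics <- lapply(poly_vids, function(pv) {
    tab <- rbind(union_tab[union_tab$vid %in% pv, , drop = FALSE], masked_tab)
    rownames(tab) <- NULL
    tab
  })
  summaries <- lapply(metrics, summarize_metrics, plans = plans)

  structure(list(config = cfg, freqs = fr, truth = truth, panels = panels,
                 prior = prior, posterior = post, chip_vids = chip_vids,
                 plans = plans, rep_posteriors = rep_posteriors,
                 metrics = metrics, summaries = summaries,
                 planted_vids = fr$planted_all),
            class = "imputation_scenario")
}

#' @export
print.imputation_scenario <- function(x, ...) {
  cat(sprintf("imputation_scenario: %d SNPs (%d planted), %d samples, %d panels, %d mask reps\n",
              x$config$n_snps, length(x$planted_vids),
              x$config$n_samples, length(x$panels), length(x$plans)))
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-8s N=%4d  rsq_mean=%.3f  maf<=2%%: %.1f%%\n",
                nm, x$panels[[nm]]$n_total, s$rsq_mean,
                100 * maf_stratum_fraction(s)))
  }
  invisible(x)
}
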