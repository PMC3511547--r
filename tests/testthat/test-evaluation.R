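# Masking harness and the three performance metrics.

test_that("mask plans have exact size, reproducibility and independence", {
  vids <- sprintf("rs%05d", 1:8101)
  plans <- build_mask_plans(vids, fraction = 0.02, reps = 10, base_seed = 99)
  expect_length(plans, 10L)
  for (pl in plans) {
    expect_length(pl$masked_vids, 162L)        # round(0.02 * 8101)
    expect_false(anyDuplicated(pl$masked_vids) > 0)
    expect_true(all(pl$masked_vids %in% vids))
  }
  plans2 <- build_mask_plans(vids, fraction = 0.02, reps = 10, base_seed = 99)
  expect_identical(plans, plans2)
  expect_false(identical(plans[[1]]$masked_vids, plans[[2]]$masked_vids))

  one <- build_mask_plans(vids[1:50], fraction = 1 / 50, reps = 2)
  expect_length(one[[1]]$masked_vids, 1L)
  expect_error(build_mask_plans(vids[1:10], fraction = 0.001, reps = 1),
               "degenerate")
})

test_that("most likely genotype is argmax with first-index tie-breaking", {
  expect_identical(most_likely_genotype(c(0.1, 0.2, 0.7)), 2L)
  expect_identical(most_likely_genotype(c(0.5, 0.5, 0)), 0L)
  expect_identical(most_likely_genotype(rep(1 / 3, 3)), 0L)
  m <- rbind(c(0.1, 0.2, 0.7), c(0.5, 0.5, 0), c(0.2, 0.6, 0.2))
  expect_identical(most_likely_genotype(m), c(2L, 0L, 1L))
})

test_that("contingency tables tally pairs and exclude missing truth", {
  t1 <- contingency(c(0L, 1L, 2L), c(0L, 1L, 2L))
  expect_equal(diag(unclass(t1)), c("0" = 1L, "1" = 1L, "2" = 1L),
               ignore_attr = TRUE)
  expect_equal(sum(t1), 3)
  t2 <- contingency(c(0L, NA), c(0L, 0L))
  expect_equal(sum(t2), 1)
  truth <- c(0L, 0L, 1L, 1L, 2L, 2L)
  imp <- c(0L, 1L, 1L, 2L, 2L, 2L)
  t3 <- contingency(truth, imp)
  hand <- matrix(0L, 3, 3)
  for (k in seq_along(truth)) hand[truth[k] + 1, imp[k] + 1] <- hand[truth[k] + 1, imp[k] + 1] + 1L
  expect_equal(unclass(t3), hand, ignore_attr = TRUE)
  expect_error(contingency(c(NA_integer_), c(0L)), "undefined")
})

test_that("concordance is trace over total", {
  d <- diag(c(5L, 3L, 2L)); class(d) <- c("contingency3", "matrix")
  expect_equal(concordance(d), 1)
  anti <- matrix(0L, 3, 3); anti[1, 3] <- 5L; anti[3, 1] <- 5L
  expect_equal(concordance(anti), 0)
  tab <- rbind(c(50L, 5L, 0L), c(4L, 30L, 6L), c(0L, 2L, 3L))
  expect_equal(concordance(tab), 83 / 100)
})

test_that("IQS equals kappa, is 0 on margin-products and undefined on one-cell tables", {
  # outer product of its own margins: observed = chance agreement
  outer_tab <- outer(c(16, 4, 0), c(16, 4, 0))
  expect_identical(iqs(outer_tab), 0)
  expect_equal(iqs(diag(c(5, 3, 2))), 1)
  one_cell <- matrix(0L, 3, 3); one_cell[1, 1] <- 17L
  expect_true(is.na(iqs(one_cell)))
  off_cell <- matrix(0L, 3, 3); off_cell[1, 2] <- 9L  # Pc = 0, P0 = 0
  expect_equal(iqs(off_cell), 0)
  set.seed(71)
  for (i in 1:300) {
    tab <- random_table3()
    if (sum(tab) == 0) next
    expect_equal(iqs(tab), kappa_oracle(tab), tolerance = 1e-12)
  }
})

test_that("variance-ratio r2hat: exact zeros, HWE identity, mixture recovery", {
  expect_equal(estimated_rsq(rep(0.6, 50)), 0)
  expect_equal(estimated_rsq(rep(0, 50)), 0)      # monomorphic dosage
  expect_equal(estimated_rsq(rep(2, 50)), 0)
  set.seed(81)
  g <- hwe_draw(10000, 0.3)
  expect_equal(estimated_rsq(g), 1, tolerance = 0.02)
  # d = q g + (1 - q) 2p has Var = q^2 2p(1-p) and mean 2p -> r2hat ~ q^2
  q <- 0.7; p <- 0.3
  d <- q * hwe_draw(10000, p) + (1 - q) * 2 * p
  # SE of the statistic estimated by independent replication
  reps <- replicate(200, {
    estimated_rsq(q * hwe_draw(10000, p) + (1 - q) * 2 * p)
  })
  expect_lt(abs(estimated_rsq(d) - q^2), 3 * sd(reps))
  expect_equal(estimated_rsq(d), 0.49, tolerance = 0.03)
})

test_that("true r2 is squared correlation with truth, NA when degenerate", {
  g <- c(0L, 1L, 2L, 1L, 0L)
  expect_equal(true_rsq(as.numeric(g), g), 1)
  expect_equal(true_rsq(2 - as.numeric(g), g), 1)   # anti-correlated
  expect_true(is.na(true_rsq(rep(1.2, 5), g)))
  expect_true(is.na(true_rsq(c(1, 2), c(NA_integer_, 1L))))
})

test_that("summaries average per rep then pool, bin correctly, and recombine", {
  per_snp <- data.frame(
    vid = c("a", "b", "c", "d", "e"),
    chrom = "1", pos = 1:5,
    rep = c(1L, 1L, 2L, NA, NA),
    maf = c(0.10, 0.30, 0.20, 0.02, 0.035),
    n_eval = c(10L, 10L, 10L, 0L, 0L),
    concordance = c(0.9, 1.0, 0.8, NA, NA),
    iqs = c(0.8, 1.0, 0.7, NA, NA),
    rsq_est = c(0.5, 0.6, 0.7, 0.40, 0.90),
    rsq_true = NA_real_)
  s <- summarize_metrics(per_snp)
  expect_equal(s$per_rep$concordance, c(0.95, 0.8))
  expect_equal(unname(s$pooled["concordance"]), mean(c(0.95, 0.8)))
  expect_equal(unname(s$pooled["iqs"]), mean(c(0.9, 0.7)))
  # rsq over the rep = NA rows only
  expect_equal(s$rsq_mean, mean(c(0.40, 0.90)))
  # MAF exactly 0.02 lands in the (0.01, 0.02] bin — the low-MAF stratum
  expect_equal(s$binned$n[s$binned$maf_hi == 0.02], 1L)
  expect_equal(maf_stratum_fraction(s, 0.02), 0.5)
  # weighted recombination of binned means reproduces rsq_mean
  b <- s$binned[s$binned$n > 0, ]
  expect_equal(sum(b$rsq_mean * b$n) / sum(b$n), s$rsq_mean, tolerance = 1e-12)
})

test_that("pooled concordance is invariant to SNP order and excludes undefined", {
  set.seed(91)
  n <- 40
  per_snp <- data.frame(
    vid = paste0("v", 1:n), chrom = "1", pos = 1:n,
    rep = rep(1:4, each = 10),
    maf = runif(n, 0.01, 0.5), n_eval = 50L,
    concordance = runif(n, 0.7, 1),
    iqs = replace(runif(n, 0.4, 1), sample(n, 5), NA),
    rsq_est = runif(n), rsq_true = NA_real_)
  s1 <- summarize_metrics(per_snp)
  s2 <- summarize_metrics(per_snp[sample(n), ])
  expect_equal(s1$pooled, s2$pooled)
  expect_equal(unname(s1$counts["n_undefined_iqs"]), 5L)
})

test_that("snp_metrics integrates the per-SNP pieces against truth", {
  set.seed(101)
  n <- 30; s <- 120
  calls <- matrix(hwe_draw(n * s, 0.25), n, s)
  truth <- make_gm(calls)
  prior <- setNames(rep(0.25, n), truth$variants$vid)
  perfect <- imputation_channel(truth, prior,
                                channel_params(base_error = 0, calibration = 1,
                                               panel_penalty = 0, maf_penalty = 0,
                                               calibration_penalty = 0))
  m <- snp_metrics(perfect, truth = truth, rep = 1L)
  expect_equal(m$concordance, rep(1, n))
  expect_true(all(m$rsq_true == 1, na.rm = TRUE))
  expect_equal(m$n_eval, rep(s, n))
  # truth-derived MAF is used when truth is available
  expect_equal(m$maf, unname(maf_from_calls(truth)), tolerance = 1e-12)
})
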