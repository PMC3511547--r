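# Panel composition and population-specific SNP filtering.

test_that("nested panel sample totals match the reference release", {
  af <- toy_af("v1", 0.1)
  expect_equal(compose_panel("close", panel_members("close"), af)$n_total, 234L)
  expect_equal(compose_panel("afr_eur", panel_members("afr_eur"), af)$n_total, 625L)
  expect_equal(compose_panel("all", panel_members("all"), af)$n_total, 1092L)
})

test_that("pooled frequencies are count-weighted means and validate inputs", {
  af <- rbind(v1 = c(YRI = 0, CEU = 0.01, ASW = 0))
  p <- compose_panel("c", data.frame(code = c("YRI", "CEU", "ASW"),
                                     count = c(88L, 85L, 61L)), af)
  expect_equal(unname(p$pooled), 0.01 * 85 / 234)
  expect_error(compose_panel("x", data.frame(code = "ZZZ", count = 5L), af),
               "unknown population")
  bad <- rbind(v1 = c(YRI = 1.3, CEU = 0.1, ASW = 0.1))
  expect_error(compose_panel("c", data.frame(code = c("YRI", "CEU", "ASW"),
                                             count = c(1L, 1L, 1L)), bad),
               "frequencies")
})

test_that("monomorphic set covers frequency 0 and fixed-ALT 1, pooling rescues", {
  vids <- c("zero", "fixed", "rescued", "common")
  af <- toy_af(vids, 0)
  af["fixed", ] <- 1
  af["rescued", ] <- 0; af["rescued", "CEU"] <- 0.01
  af["common", ] <- 0.3
  p <- compose_panel("close", panel_members("close"), af)
  expect_setequal(monomorphic_set(p), c("zero", "fixed"))
})

test_that("monomorphic set is monotone under panel growth", {
  set.seed(5)
  vids <- paste0("v", 1:60)
  af <- toy_af(vids, 0)
  pops <- kg_populations()$code
  for (v in vids) af[v, sample(pops, sample(0:6, 1))] <- runif(1, 0, 0.4)
  small <- compose_panel("close", panel_members("close"), af)
  mid <- compose_panel("afr_eur", panel_members("afr_eur"), af)
  big <- compose_panel("all", panel_members("all"), af)
  expect_true(all(monomorphic_set(mid) %in% monomorphic_set(small)))
  expect_true(all(monomorphic_set(big) %in% monomorphic_set(mid)))
})

test_that("pre-imputation filter removes the monomorphic subset exactly", {
  vids <- paste0("v", 1:10)
  af <- toy_af(vids, 0.2)
  af[1:3, ] <- 0
  p <- compose_panel("close", panel_members("close"), af)
  res <- pre_impute_filter(vids, p)
  expect_setequal(res$removed_vids, vids[1:3])
  expect_setequal(res$kept_vids, vids[4:10])
  expect_identical(res$reason, "monomorphic-in-subpanel")
  # uncovered variants are treated as monomorphic in the panel
  res2 <- pre_impute_filter(c(vids, "not_in_panel"), p)
  expect_true("not_in_panel" %in% res2$removed_vids)
  # empty monomorphic set: identity
  af_poly <- toy_af(vids, 0.2)
  p2 <- compose_panel("close", panel_members("close"), af_poly)
  expect_setequal(pre_impute_filter(vids, p2)$kept_vids, vids)
  # all monomorphic: degenerate warning
  p3 <- compose_panel("close", panel_members("close"), toy_af(vids, 0))
  expect_warning(res3 <- pre_impute_filter(vids, p3), "degenerate")
  expect_length(res3$kept_vids, 0L)
})

test_that("filters partition the input exactly", {
  vids <- paste0("v", 1:20)
  af <- toy_af(vids, 0.2); af[1:6, ] <- 0
  p <- compose_panel("all", panel_members("all"), af)
  res <- pre_impute_filter(vids, p)
  expect_setequal(c(res$kept_vids, res$removed_vids), vids)
  expect_length(intersect(res$kept_vids, res$removed_vids), 0L)

  metrics <- data.frame(vid = vids, chrom = "1", pos = 1:20, rep = NA_integer_,
                        maf = 0.1, n_eval = 0L, concordance = NA_real_,
                        iqs = NA_real_, rsq_est = seq(0, 0.95, by = 0.05),
                        rsq_true = NA_real_)
  fr <- rsq_threshold_filter(metrics, 0.3)
  expect_setequal(c(fr$kept_vids, fr$removed_vids), vids)
})

test_that("r2hat threshold is inclusive at the boundary", {
  metrics <- data.frame(vid = c("lo", "edge", "hi"), chrom = "1", pos = 1:3,
                        rep = NA_integer_, maf = 0.1, n_eval = 0L,
                        concordance = NA_real_, iqs = NA_real_,
                        rsq_est = c(0.29, 0.30, 0.80), rsq_true = NA_real_)
  fr <- rsq_threshold_filter(metrics, 0.3)
  expect_setequal(fr$kept_vids, c("edge", "hi"))
  expect_identical(fr$removed_vids, "lo")
})

test_that("post-imputation filtering removes the planted set and lifts mean r2hat", {
  # planted design: 40% of SNPs monomorphic in the close subpanel with poor
  # r2hat (~0.2), the rest polymorphic with good r2hat (~0.8)
  set.seed(15)
  n <- 100
  vids <- paste0("v", seq_len(n))
  planted <- vids[1:40]
  af <- toy_af(vids, 0.25)
  af[planted, c("YRI", "CEU", "ASW")] <- 0
  close <- compose_panel("close", panel_members("close"), af)
  metrics <- data.frame(vid = vids, chrom = "1", pos = seq_len(n),
                        rep = NA_integer_,
                        maf = runif(n, 0.05, 0.45), n_eval = 0L,
                        concordance = NA_real_, iqs = NA_real_,
                        rsq_est = c(runif(40, 0.15, 0.25), runif(60, 0.75, 0.85)),
                        rsq_true = NA_real_)
  unfiltered <- summarize_metrics(metrics)
  res <- post_impute_filter(metrics, close)
  expect_setequal(res$filter$removed_vids, planted)
  expect_gt(res$summary$rsq_mean, unfiltered$rsq_mean)
  # empty monomorphic set leaves the summary unchanged
  all_poly <- compose_panel("close", panel_members("close"), toy_af(vids, 0.25))
  res2 <- post_impute_filter(metrics, all_poly)
  expect_length(res2$filter$removed_vids, 0L)
  expect_equal(res2$summary$rsq_mean, unfiltered$rsq_mean)
})

test_that("threshold filtering reduces but does not eliminate planted SNPs", {
  # channel built so planted SNPs straddle the 0.3 threshold
  set.seed(25)
  n <- 80
  vids <- paste0("v", seq_len(n))
  planted <- vids[1:30]
  metrics <- data.frame(vid = vids, chrom = "1", pos = seq_len(n),
                        rep = NA_integer_, maf = 0.05, n_eval = 0L,
                        concordance = NA_real_, iqs = NA_real_,
                        rsq_est = c(runif(30, 0.1, 0.5), runif(50, 0.6, 0.9)),
                        rsq_true = NA_real_)
  fr <- rsq_threshold_filter(metrics, 0.3)
  survivors <- intersect(fr$kept_vids, planted)
  expect_gt(length(survivors), 0L)
  expect_lt(length(survivors), length(planted))
})

test_that("exclusion lists round-trip as one vid per line", {
  f <- withr::local_tempfile()
  write_exclusion_list(c("rs1", "rs2"), f)
  expect_identical(readLines(f), c("rs1", "rs2"))
})
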