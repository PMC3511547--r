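# Readers, writers and allele harmonization.

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

vcf_header <- function(samples, fmt = "GT") {
  c("##fileformat=VCFv4.2",
    sprintf("##FORMAT=<ID=%s,Number=.,Type=String,Description=\"x\">", fmt),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("VCF genotypes parse; indels and multiallelics are skipped with counts", {
  lines <- c(vcf_header(c("sampA", "sampB")),
             "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
             "1\t200\trs2\tC\tT\t.\t.\t.\tGT\t1/1\t0|1",
             "1\t300\trs3\tG\tA\t.\t.\t.\tGT\t0/0\t1/1")
  g <- read_genotypes(write_lines_tmp(lines), "vcf")
  expect_equal(dim(g), c(3L, 2L))
  expect_false(anyNA(g$calls))
  expect_equal(unname(g$calls[, "sampB"]), c(1L, 1L, 2L))

  with_indel <- c(vcf_header("sampA"),
                  "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0",
                  "1\t150\trs2\tA\tAT\t.\t.\t.\tGT\t0/1",  # indel
                  "1\t200\trs3\tC\tT\t.\t.\t.\tGT\t1/1",
                  "1\t250\trs4\tG\tC\t.\t.\t.\tGT\t0/1",
                  "1\t300\trs5\tT\tA\t.\t.\t.\tGT\t0/0")
  g2 <- read_genotypes(write_lines_tmp(with_indel), "vcf")
  expect_equal(nrow(g2$calls), 4L)
  expect_equal(attr(g2, "n_skipped_indel"), 1L)

  half <- c(vcf_header("sampA"),
            "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t./1")
  expect_true(is.na(read_genotypes(write_lines_tmp(half), "vcf")$calls[1, 1]))
})

test_that("matrix-text round-trips and propagates missing tokens", {
  lines <- c("chrom\tpos\tvid\tref\talt\ts1\ts2",
             "1\t100\tv1\tA\tG\t0\t2",
             "1\t200\tv2\tC\tT\t./.\t1")
  g <- read_genotypes(write_lines_tmp(lines), "matrix-text")
  expect_true(is.na(g$calls["v2", "s1"]))
  expect_equal(g$calls["v1", "s2"], 2L)

  f <- withr::local_tempfile()
  write_genotypes(g, f, "matrix-text")
  g2 <- read_genotypes(f, "matrix-text")
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$variants, g$variants)

  fv <- withr::local_tempfile()
  write_genotypes(g, fv, "vcf")
  g3 <- read_genotypes(fv, "vcf")
  expect_identical(unname(g3$calls), unname(g$calls))
})

test_that("GEN triplets load, renormalize, and reject malformed sums", {
  lines <- c("1 v1 100 A G 0 0 1 1 0 0",
             "1 v2 200 C T 0.2 0.2 0.2 0.5 0.5 0")
  p <- read_imputed(write_lines_tmp(lines), "gen-triplet")
  expect_equal(dosages(p)["v1", "S1"], 2)
  expect_equal(unname(c(p$p0["v2", "S1"], p$p1["v2", "S1"], p$p2["v2", "S1"])),
               rep(1 / 3, 3), tolerance = 1e-12)
  bad <- "1 v1 100 A G 0.5 0.5 0.5"
  expect_error(read_imputed(write_lines_tmp(bad), "gen-triplet"), "malformed")
  zero <- "1 v1 100 A G 0 0 0"
  expect_error(read_imputed(write_lines_tmp(zero), "gen-triplet"), "malformed")
  ragged <- c("1 v1 100 A G 0 0 1 1", "1 v2 200 C T 0 1 0 0")
  expect_error(read_imputed(write_lines_tmp(ragged), "gen-triplet"), "malformed")
})

test_that("dosage input expands to the adjacent-integer posterior", {
  lines <- c("s1->s1\tML_DOSE\t1.5\t0",
             "s2->s2\tML_DOSE\t2\t0.25")
  p <- read_imputed(write_lines_tmp(lines), "dosage")
  expect_true(p$dosage_derived)
  expect_equal(unname(c(p$p0[1, "s1"], p$p1[1, "s1"], p$p2[1, "s1"])),
               c(0, 0.5, 0.5))
  expect_equal(unname(c(p$p0[1, "s2"], p$p1[1, "s2"], p$p2[1, "s2"])),
               c(0, 0, 1))
  # dosage is preserved by the expansion
  expect_equal(unname(dosages(p)[, "s2"]), c(2, 0.25))
})

test_that("write/read round-trips preserve triplets and dosages within 1e-6", {
  set.seed(7)
  n <- 6; s <- 4
  v <- variant_table(rep("2", n), 1:n * 10, paste0("v", 1:n),
                     rep("A", n), rep("C", n))
  raw <- matrix(runif(n * s * 3), n * s, 3)
  raw <- raw / rowSums(raw)
  p <- posterior_matrix(v, paste0("s", 1:s),
                        matrix(raw[, 1], n), matrix(raw[, 2], n),
                        matrix(raw[, 3], n))
  for (fmt in c("gen-triplet", "vcf-gp")) {
    f <- withr::local_tempfile()
    write_imputed(p, f, fmt)
    p2 <- read_imputed(f, fmt, samples = if (fmt == "gen-triplet") p$samples)
    expect_equal(unname(p2$p0), unname(p$p0), tolerance = 1e-6)
    expect_equal(unname(p2$p2), unname(p$p2), tolerance = 1e-6)
  }
  f <- withr::local_tempfile()
  write_imputed(p, f, "dosage")
  p3 <- read_imputed(f, "dosage", variants = v)
  expect_equal(unname(dosages(p3)), unname(dosages(p)), tolerance = 1e-6)
})

test_that("allele harmonization handles swaps, strand flips and ambiguity", {
  tv <- variant_table(c("1", "1", "1", "1"), c(100, 200, 300, 400),
                      paste0("t", 1:4),
                      c("A", "A", "A", "C"), c("G", "G", "T", "T"))
  truth <- genotype_matrix(tv, c("x", "y"), matrix(0L, 4, 2))
  iv <- variant_table(c("1", "1", "1", "1"), c(100, 200, 300, 400),
                      paste0("i", 1:4),
                      c("G", "T", "T", "A"), c("A", "C", "A", "G"))
  p0 <- matrix(c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7), 4, 2)
  p1 <- matrix(0.2, 4, 2)
  p2 <- matrix(0.1, 4, 2)
  imp <- posterior_matrix(iv, c("x", "y"), p0, p1, p2)
  out <- align_alleles(imp, truth)
  cnt <- attr(out, "align_counts")
  # t1: swapped labels -> triplet reversed
  expect_equal(unname(out$p0["t1", "x"]), 0.1)
  expect_equal(unname(out$p2["t1", "x"]), 0.7)
  # t2: strand complement (T/C -> A/G), no swap, unchanged
  expect_equal(unname(out$p0["t2", "x"]), 0.7)
  # t3: truth A/T ambiguous, imputed T/A -> excluded
  expect_false("t3" %in% out$variants$vid)
  expect_equal(unname(cnt["ambiguous_excluded"]), 1L)
  # t4: C/T truth vs G/A imputed -> complement+swap -> reversed
  expect_equal(unname(out$p0["t4", "x"]), 0.1)

  # idempotent, and dosage preserved under double application
  out2 <- align_alleles(out, truth)
  expect_equal(unname(out2$p0), unname(out$p0))
  expect_equal(unname(dosages(out2)), unname(dosages(out)))
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(read_genotypes(tempfile(), "vcf"), "cannot read")
  only_indel <- c(vcf_header("sampA"),
                  "1\t150\trs2\tA\tAT\t.\t.\t.\tGT\t0/1")
  expect_error(read_genotypes(write_lines_tmp(only_indel), "vcf"), "empty dataset")
  expect_error(variant_table("1", 1, "v", "A", "A"), "invalid")
  expect_error(variant_table(c("1", "1"), c(1, 1), c("a", "b"),
                             c("A", "A"), c("G", "G")), "duplicate")
})
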