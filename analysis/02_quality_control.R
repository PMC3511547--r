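#!/usr/bin/env Rscript
# Stage 2 — quality control.
#
# (a) SNP-level QC (MAF < 1%, call rate < 95%, exact HWE p < 1e-4) on the
#     simulated chip genotypes.
# (b) Subject-level QC demonstrated on a dedicated relatedness simulation:
#     the robust kinship threshold (0.0441) presumes genome-scale marker
#     counts, so duplicates / parent-offspring pairs / unrelateds are
#     planted over 5000 common SNPs where the estimator resolves them.

library(imputeval)

dir.create("results", showWarnings = FALSE)

## (a) SNP-level QC on the study chip -----------------------------------
cfg <- sim_config(seed = 1, missing_rate = 0.02)
fr <- simulate_population_freqs(cfg)
truth <- simulate_genotypes(fr, cfg)
sq <- snp_qc(truth, qc_thresholds())
cat(sprintf("SNP QC: %d -> %d variants (removed %d MAF, %d call rate, %d HWE)\n",
            cfg$n_snps, sq$report$retained[["variants"]],
            sq$report$snps_removed[["maf"]],
            sq$report$snps_removed[["call_rate"]],
            sq$report$snps_removed[["hwe"]]))
write_qc_report(sq$report, "results/02_snp_qc.json")

## (b) subject-level QC: planted duplicate, relatives, ancestry outliers --
set.seed(2)
m <- 5000
p <- runif(m, 0.1, 0.5)
a1 <- rbinom(m, 1, p); a2 <- rbinom(m, 1, p)
parent <- a1 + a2
child <- ifelse(runif(m) < 0.5, a1, a2) + rbinom(m, 1, p)
dup <- parent; dup[sample(m, 100)] <- NA            # duplicate, lower call rate
unrelated <- replicate(4, rbinom(m, 2, p))
calls <- cbind(parent, dup, child, unrelated)
v <- variant_table(rep("1", m), seq_len(m), sprintf("q%04d", seq_len(m)),
                   rep("A", m), rep("G", m))
g <- genotype_matrix(v, c("parent", "parent_dup", "child", paste0("u", 1:4)), calls)

dres <- duplicate_prune(g)
cat(sprintf("duplicate prune (IBS > 99%%): removed %s\n",
            paste(dres$removed, collapse = ", ")))
g <- genotype_matrix(g$variants, dres$retained, g$calls[, dres$retained])
kres <- kinship_prune(g)
cat(sprintf("kinship prune (phi > 0.0441): parent-child phi = %.3f, removed %s\n",
            kres$kinship["parent", "child"], paste(kres$removed, collapse = ", ")))

anc <- data.frame(sample = kres$retained,
                  African = c(0.85, 0.55, 0.92, 0.78, 0.70)[seq_along(kres$retained)],
                  stringsAsFactors = FALSE)
anc$European <- 1 - anc$African
ares <- ancestry_filter(anc, qc_thresholds())
cat(sprintf("ancestry filter (<60%% African): removed %s\n",
            paste(ares$removed, collapse = ", ")))

write_qc_report(list(duplicates = dres$removed, relatives = kres$removed,
                     ancestry_outliers = ares$removed,
                     retained = ares$retained),
                "results/02_subject_qc.json")
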