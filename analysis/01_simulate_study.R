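#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study population.
#
# Builds the default study conditions: 3000 SNPs (2000 shared across all
# reference populations, 500 monomorphic in the close panel's populations,
# 500 additionally monomorphic in the African/European extension), a
# rare-weighted ancestral MAF spectrum, Balding-Nichols divergence across
# the fourteen reference populations, and 200 study subjects admixed
# Beta(8, 2) between the African and European ancestral populations.
# Writes the frequency table and study genotypes under results/.

library(imputeval)

cfg <- sim_config(seed = 1)
fr <- simulate_population_freqs(cfg)
truth <- simulate_genotypes(fr, cfg)
info <- attr(truth, "sample_info")

dir.create("results", showWarnings = FALSE)
write.table(data.frame(vid = fr$vids, ancestral = fr$anc, round(fr$af, 5)),
            "results/01_population_freqs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
# the full genotype matrix is bulky, regeneratable output: park it in scratch/
dir.create("scratch", showWarnings = FALSE)
write_genotypes(truth, "scratch/01_truth_genotypes.txt", "matrix-text")
write.table(info, "results/01_sample_ancestry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

maf <- maf_from_calls(truth)
cat(sprintf("simulated %d SNPs x %d samples\n", cfg$n_snps, cfg$n_samples))
cat(sprintf("planted population-specific SNPs: %d (close) + %d (close+afr_eur)\n",
            length(fr$planted[[1]]), length(fr$planted[[2]])))
cat(sprintf("study MAF spectrum: %.0f%% of shared SNPs at MAF <= 2%%\n",
            100 * mean(maf[!fr$vids %in% fr$planted_all] <= 0.02)))
cat(sprintf("mean African ancestry: %.2f (%d samples below the 60%% threshold)\n",
            mean(info$african), sum(info$african < 0.6)))
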