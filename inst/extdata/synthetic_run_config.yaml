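# Example file-sourced run over the bundled synthetic fixtures.
source: files
truth_path: inst/extdata/synthetic_truth.vcf
truth_format: vcf
imputed_path: inst/extdata/synthetic_imputed.gen
imputed_format: gen-triplet
imputed_samples: [NA19001, NA19002, NA19003, NA19004]
run_qc: false
filters: [rsq-threshold]
rsq_threshold: 0.3
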