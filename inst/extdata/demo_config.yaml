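# demo pipeline configuration (see nilqtl::default_pipeline_config())
seed: 42
n_segregants: 77
n_replicates: 2
n_permutations: 1000
trait: RS
expected_max: 125
n_snps: 2000
snp_common_fraction: 0.8
tiling_fdr: 0.65
tiling_jitter_sd: 5
match_window: 20
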