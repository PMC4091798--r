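# Bundled synthetic-study configuration: a four-cell-type unreplicated
# design (one focal germline cell type with two arrays plus RNA-seq; three
# comparison cell types with RNA-seq only), sized to run the whole pipeline
# in well under a minute.
seed: 42
n_genes: 300
variants_per_gene: [1, 2, 3]
mean_length: 1000
sd_length: 200
probe_divergence_rate: 0.02
background_mean: 6
background_sd: 1
signal_mean: 9
signal_sd: 1
dispersion: 0.64
library_sizes: [100000, 100000, 100000, 100000]
expressed_fraction: 0.6
de_fraction: 0.1
fold_change: 4
n_probesets: 150
probes_per_set: 11
off_target_fraction: 0.3
n_arrays: 2
max_mismatches: 3
p_present: 0.02
min_negatives: 20
min_total_len: 100
min_reads: 5
q: 0.9
fdr_cut: 0.05
raw_cut: 0.001
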