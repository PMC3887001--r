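# polyLD demo run: small three-population panel (two tetraploid, one
# diploid) with LD decaying on a 1-Mbp chromosome.
n_e = 100
n_loci = 120
chrom_length = 1000000
rec_rate = 1e-7
n_generations = 300
n_subpops = 3
split_generation = 200
founder_freq_low = 0.1
founder_freq_high = 0.9
samples_per_pop = 25
ploidy_per_pop = 4,4,2
missing_rate = 0.01
maf = 0.05
n_pcs = 5
k_min = 1
k_max = 6
r2_target = 0.2
max_d = 1000000
windows = 100000,200000,1000000
variant = sved
stages = qc,structure,ld,consistency
seed = 20
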