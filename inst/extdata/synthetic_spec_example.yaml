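# Example generator specification for `resibind.R simulate --spec ... --out ...`
n_sequences: 50
length_range: [80, 120]
pos_rate: 0.06      # target binding-residue fraction (benchmarks run 5-9%)
run_length: 5       # mean length of contiguous binding stretches
dim: 16             # embedding dimension
separation: 2       # class-mean distance in embedding space
noise_sd: 1
seed: 1
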