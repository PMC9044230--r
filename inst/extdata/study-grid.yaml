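# Full study grid: 3 communality structures x 3 non-normality scenarios x the
# 27-value sample-size ladder (omit sample_sizes to use the ladder), 10
# replicates, all five reducers with a 3-unit bottleneck and an 80/20 split.
structures: [high, wide, low]
scenarios: [s1, s2, s3]
replicates: 10
train_fraction: 0.8
master_seed: 1
variants: [pca, simple_ae, tied_ae, deep_ae, independent_ae]
k: 3
control:
  epochs: 500
  batch_size: 32
  patience: 50
  min_delta: 1.0e-6
out_dir: grid-output
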