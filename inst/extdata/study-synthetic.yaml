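# Example study configuration: leave-one-out extrapolation on a small
# generated lexicon.  Paths to association/co-occurrence/norm files can
# replace the `synthetic` block to run on real data.
design: loo
seed: 1
n_rand: 500
k_grid: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 15, 20, 30, 40, 50]
synthetic:
  vocab_size: 200
  latent_dim: 8
  participants: 40
  raters: 10
  properties:
    valence: [1, 7]
    arousal: [1, 7]
    aoa: [2, 16]
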