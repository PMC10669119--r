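# Example study configuration: two synthetic variants, short analysis
# window and a small surrogate count so it runs in seconds.
inputs:
  - preset: FSE-like
    orientation: coronal
  - preset: CINE-like
    orientation: axial
analysis_window: 2
puff_source: auto
seg_params:
  envelope_window: 0.005
  threshold_k: 1.5
kpss:
  variant: trend
  alpha: 0.05
tf:
  J: 50
  win_frac: [0.05]
  puff_win_frac: 0.2
seed: 7
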