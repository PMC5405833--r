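# Example run configuration for `fesgait run`.
subject: A
sides: [left]
seed: 1
sensor:
  k: 0.3              # adaptive threshold fraction of the signal range
  hysteresis: 0.1     # FSR Schmitt-trigger band (fraction of threshold)
  hip_hysteresis: 0   # hip channel: smooth angle, no dead band
  theta_h_frac: 0.6   # hip threshold as fraction of peak flexion
  mode: batch         # or "sliding" for a causal trailing window
  window: 400         # sliding-window width in samples
  blend: 0.98         # complementary-filter blend at 100 Hz
fsm:
  initial_phase: ST
analysis:
  n_keep: 30
  alpha: 0.05
  alpha_corrected: 0.004
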