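# Per-subject stimulation setup parameters measured during the preparation
# session. For each muscle (TA tibialis anterior, LG lateral gastrocnemius,
# BF biceps femoris, RF rectus femoris) and side (L/R), cmin is the minimum
# current (mA) eliciting a visible contraction and cmax the maximum current
# producing a maximal contraction. Stimulation pulse width in microseconds,
# frequency in Hz. Optional per-channel `fc` (Hz) overrides the default
# envelope cutoff.
pulse_width: 350
stim_frequency: 40
subjects:
  A:
    LTA: {cmin: 10, cmax: 20}
    LLG: {cmin: 16, cmax: 22}
    LBF: {cmin: 14, cmax: 26}
    LRF: {cmin: 14, cmax: 20}
    RTA: {cmin: 12, cmax: 18}
    RLG: {cmin: 12, cmax: 14}
    RBF: {cmin: 18, cmax: 22}
    RRF: {cmin: 14, cmax: 22}
  B:
    LTA: {cmin: 6, cmax: 24}
    LLG: {cmin: 14, cmax: 28}
    LBF: {cmin: 8, cmax: 22}
    LRF: {cmin: 12, cmax: 22}
    RTA: {cmin: 10, cmax: 22}
    RLG: {cmin: 12, cmax: 24}
    RBF: {cmin: 10, cmax: 22}
    RRF: {cmin: 14, cmax: 24}
  C:
    LTA: {cmin: 8, cmax: 12}
    LLG: {cmin: 8, cmax: 12}
    LBF: {cmin: 10, cmax: 14}
    LRF: {cmin: 10, cmax: 16}
    RTA: {cmin: 6, cmax: 10}
    RLG: {cmin: 6, cmax: 10}
    RBF: {cmin: 10, cmax: 14}
    RRF: {cmin: 10, cmax: 14}
  D:
    LTA: {cmin: 10, cmax: 14}
    LLG: {cmin: 10, cmax: 14}
    LBF: {cmin: 16, cmax: 22}
    LRF: {cmin: 6, cmax: 18}
    RTA: {cmin: 10, cmax: 22}
    RLG: {cmin: 14, cmax: 22}
    RBF: {cmin: 14, cmax: 24}
    RRF: {cmin: 18, cmax: 26}
  E:
    LTA: {cmin: 8, cmax: 20}
    LLG: {cmin: 8, cmax: 20}
    LBF: {cmin: 14, cmax: 22}
    LRF: {cmin: 14, cmax: 22}
    RTA: {cmin: 8, cmax: 14}
    RLG: {cmin: 8, cmax: 26}
    RBF: {cmin: 14, cmax: 24}
    RRF: {cmin: 14, cmax: 24}
  F:
    LTA: {cmin: 10, cmax: 24}
    LLG: {cmin: 12, cmax: 24}
    LBF: {cmin: 16, cmax: 26}
    LRF: {cmin: 18, cmax: 30}
    RTA: {cmin: 10, cmax: 24}
    RLG: {cmin: 16, cmax: 26}
    RBF: {cmin: 24, cmax: 30}
    RRF: {cmin: 16, cmax: 30}
  G:
    LTA: {cmin: 12, cmax: 22}
    LLG: {cmin: 6, cmax: 20}
    LBF: {cmin: 14, cmax: 24}
    LRF: {cmin: 12, cmax: 28}
    RTA: {cmin: 14, cmax: 24}
    RLG: {cmin: 10, cmax: 24}
    RBF: {cmin: 10, cmax: 24}
    RRF: {cmin: 10, cmax: 28}
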