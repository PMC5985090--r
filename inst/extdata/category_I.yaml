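fs: 128.0
trial_seconds: 10.0
n_trials_per_class: 20
rhythm_freqs:
- 10.0
- 22.0
rhythm_amp: 6.0
noise_sigma: 14.0
noise_spectrum: white
blink_rate: 0.6
blink_amp: 400.0
blink_channels:
- AF3
- AF4
- F3
- F4
- F7
- F8
seed: 1
class_gains:
  thumb:
  - 1.0
  - 1.0
  - 1.7
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  index:
  - 1.0
  - 1.0
  - 1.0
  - 1.7
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  fist:
  - 1.0
  - 1.0
  - 2.3
  - 2.3
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
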