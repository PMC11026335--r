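{
  "younger": {
    "n_voxels": 50,
    "w_ctx": 0.9,
    "w_mne_epi": 0.3,
    "w_mne_sem": 0.15,
    "w_ff": 1.0,
    "noise_sd": 1.0
  },
  "older": {
    "n_voxels": 50,
    "w_ctx": 0.45,
    "w_mne_epi": 0.3,
    "w_mne_sem": 0.3,
    "w_ff": 0.6,
    "noise_sd": 1.2
  }
}
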