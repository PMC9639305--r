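{
  "master_seed": 20260909,
  "sites": [
    {
      "label": "vendorA",
      "count": 4,
      "template": {
        "grid_size": 128,
        "remote_sd": 0.016,
        "infarct_center_angle": [0, 360],
        "infarct_extent": [60, 150],
        "transmurality": [0.5, 1.0],
        "bias_amplitude": 0.15,
        "noise_model": "rician"
      }
    },
    {
      "label": "vendorB",
      "count": 4,
      "template": {
        "grid_size": 128,
        "remote_sd": 0.026,
        "infarct_center_angle": [0, 360],
        "infarct_extent": [60, 150],
        "transmurality": [0.5, 1.0],
        "bias_amplitude": 0.15,
        "noise_model": "noncentral_chi",
        "coil_count": 8
      }
    },
    {
      "label": "vendorC",
      "count": 4,
      "template": {
        "grid_size": 128,
        "remote_sd": 0.013,
        "infarct_center_angle": [0, 360],
        "infarct_extent": [60, 150],
        "transmurality": [0.5, 1.0],
        "bias_amplitude": 0.15,
        "noise_model": "gaussian"
      }
    }
  ]
}
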