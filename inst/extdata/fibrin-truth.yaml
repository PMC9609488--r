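case: fibrin
type: orientation
n_vp: 1
theta_vp_deg: 90.0
k2d: 0.98
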