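# Example reconstruction configuration. Omitted keys take the package
# defaults (see ?tuns_params); unknown keys are rejected.
lambda1: 0.02
lambda2: 10
lambda3: 5
lambda4: 1
max_iter: 300
tol: 1.0e-6
kernel:
  kind: rbf
  bandwidth: median
  median_scale: 0.5
center_tracks: true
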