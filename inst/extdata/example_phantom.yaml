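# Example phantom specification for `elastnet simulate`.
# A 10-frame sequence (9 cumulative strain levels, 0.5 %..4.5 %) with one
# stiff inclusion; grid kept small for quick experiments.
grid_shape: [64, 64]
scatterer_density: 1.5
inclusions:
  - [0.5, 0.5, 0.15, 0.5]     # center_axial, center_lateral, radius, contrast
strain_schedule: [0.005, 0.01, 0.015, 0.02, 0.025, 0.03, 0.035, 0.04, 0.045]
lateral_drift: 0.3
noise_sigma: 0.05
psf: [0.25, 2.0, 1.5]          # cycles/sample, axial sigma, lateral sigma
poisson_ratio: 0.495
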