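# Mirrored two-layer folds in a pressure-driven air channel (mIFEM).
case: folds
algorithm: mifem
dt: 1.0e-5
n_steps: 60
seed: 1
geometry:
  scale: 0.02   # inlet pressure = scale * 1 kPa
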