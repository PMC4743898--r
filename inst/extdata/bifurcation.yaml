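# Cell in a bifurcated microvessel (explicit IFEM), desk scale.
case: bifurcation
algorithm: ifem
dt: 2.0e-5
n_steps: 1800
seed: 1
geometry:
  r_d: 1        # diameter ratio w1/w2 of the daughter branches
  flow_ratio: 3 # Q1/Q2 outlet flow split
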