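# equilibrium scan of the Ime2 auto-regulation half-maximum constant
experiment: scan
param: c2
range: [0.1, 2.0]
n_steps: 25
hill_n: 5
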