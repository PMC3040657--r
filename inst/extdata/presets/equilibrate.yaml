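# Free dynamics of the bent model (equilibration / stability check)
protocol:
  preset: equilibrate
params:
  temperature: 300
  duration: 5
seed: 1
out: runs/equilibrate
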