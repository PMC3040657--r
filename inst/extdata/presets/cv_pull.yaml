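# Constant-velocity unbending: virtual spring k = 0.5 kcal/mol/A^2 moving
# at 1 A/ns, pulling the betaA-domain COM away from the tethered betaTD
protocol:
  preset: cv_pull
  kKcal: 0.5
  v: 1
params:
  temperature: 300
  duration: 60
seed: 1
analysis:
  sasaPoints: 240
  stride: 4
out: runs/cv_pull
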