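# Constant-force series on the five-force design used for Bell analysis
protocol:
  preset: cf_pull
  forces: [97, 122, 146, 170, 195]
params:
  temperature: 300
  duration: 60
kinetics:
  baselineWindow: 1
  delta: 20
  holdTime: 1
seed: 1
out: runs/cf_series
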