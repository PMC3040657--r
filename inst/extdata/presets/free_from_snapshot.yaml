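# Free dynamics restarted from a pulled snapshot (rebending / stability)
protocol:
  preset: free_from_snapshot
params:
  temperature: 300
  duration: 25
seed: 1
out: runs/free_snapshot
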