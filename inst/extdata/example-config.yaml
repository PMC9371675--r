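# Example run configuration: NHEJ-only resistance, one gRNA.
params:
  m: 1
  K: 2632          # overridden by run.NGrid below
  beta: 0.01
  mu: 0
  sigma: 0.01
theory:
  gammaN: 0.2
run:
  NGrid: [500, 1000, 2000, 4000, 8000, 13000]
  nReps: 200
  baseSeed: 1
  outputDir: runs/nhej-m1
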