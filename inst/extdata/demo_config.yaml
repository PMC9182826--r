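# demo configuration: simulate a small cohort and run the full pipeline
seed: 42
output_dir: grsmr_demo
scenario:
  nSamples: 2000
  nSnps: 12
  ldBlockSize: 2
  ldRho: 0.4
  baselineHazard: 0.01
  missingRate: 0.02
  prevalentRate: 0.005
  seed: 42
exposures:
  - name: exposure_sim
    unit: 1
    model: observational
alpha: 0.05
bonferroni_k: 28
grs:
  p_threshold: 5.0e-8
  ld_r2: 0.1
n_boot: 500
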