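# Example pipeline configuration: fields overlay defaultPipelineConfig().
# Lengths in mm, stresses dimensionless on the 0-100 scaled axis.
seed: 1
phantom:
  noiseSD: 50
coarsening:
  level: 2
crop:
  proximalFraction: 0.15
  distalFraction: 0.15
load:
  bodyMass: 80
optimize:
  threshold: 0.2
  stopCap: 84
  maxSteps: 10
  perStepMax: true
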