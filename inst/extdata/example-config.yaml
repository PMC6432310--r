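# Example configuration for the command-line driver (inst/cli/fgmem.R).
# Model 1 reference point: lambda = 0.2, kappa = 7, c = 5, phi0 = 0.7.
lattice:
  subdivision: 3
model:
  variant: model1
  lambda: 0.2
  kappa: 7
  c: 5
  phi0: 0.7
schedule:
  therm_sweeps: 500
  meas_sweeps: 1500
  meas_interval: 25
  tune_interval: 100
output:
  dir: fgmem-out
seed: 1
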