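# srnaqic experiment config template.
# Unknown keys are rejected; omitted keys take the documented defaults and
# are materialized into the resolved config echoed to stderr on each run.

# Required: what to run.
#   simulate | step | robustness | sweep | qic-check | silencing
experiment: step

# Model variant: regulated (default) | unregulated | full | ideal.
variant: regulated

# Parameter source: a fixture name (see device_fixture_names()) and/or a
# params block. With a fixture, params entries act as overrides.
fixture: strong-high-regulated
params:
  delta: 8        # uncoupled mRNA/sRNA decay, 1/h
  # T_rate: 300   # transcription rate per DNA copy, nM/h
  # D: 10         # plasmid copy number
  # kappa_gfp: 100  # output RBS dissociation constant, nM
  # k: 6.6468     # feedback gain (kappa_ecf is re-derived)
  # Ts: 50        # lumped sRNA transcription rate, 1/h
  # lam: 2000     # coupled mRNA-sRNA decay, 1/h
  # beta: 1       # mRNA-sRNA binding dissociation constant, nM
  # R: 1000       # max translation rate, nM/h
  # gamma: 1.4    # protein decay/dilution, 1/h
  # actuator_saturation: 50  # optional sensor half-saturation, nM

# Transcription-factor input to H(u1); irrelevant for constitutive devices.
u1: 1

# Disturbance: either a constant 0 <= d < 1 ...
disturbance:
  d: 0
# ... or a piecewise-constant profile on half-open intervals:
# disturbance:
#   breakpoints: [-.inf, 0, 4]
#   values: [0, 0.5, 0.2]

# simulate: time window
t_span: [0, 10]

# step / robustness / sweep: disturbance magnitude
d: 0.5
# step: horizon after the step (default 8/gamma hours)
horizon: 6

# qic-check: pass threshold for the three condition ratios
epsilon: 0.1

# sweep: axis (gain | disturbance | input) and its values
axis: disturbance
values: [0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]

# silencing: inducer doses and the Hill induction of the sensor
doses: [0, 1, 3, 10, 30, 100, 300, 1000]
K_half: 30
hill_n: 1
basal: 0
sensor_max: 100   # fully induced sensor concentration, nM

# Solver controls
solver:
  rtol: 1.0e-08
  atol: 1.0e-10
  n_grid: 500

# Output file: CSV for trajectories/sweeps/dose responses, JSON for
# robustness and qic-check reports. No timestamps: identical configs give
# byte-identical files.
# out: results/step.csv
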