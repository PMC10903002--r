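# Simulation configuration template.  All keys are optional; omitted keys
# fall back to the packaged defaults shown here.  The trajectory values are
# the packaged synthetic fixture for an amyloid-positive MCI cohort; replace
# them with estimated visit means and covariance if available.
visit_months: [0, 6, 12, 18, 24, 36]
placebo_means: [1.50, 1.65, 1.95, 2.40, 2.95, 4.05]
covariance:
  - [1.000, 1.074, 1.209, 1.314, 1.397, 1.466]
  - [1.074, 1.440, 1.611, 1.740, 1.839, 1.905]
  - [1.209, 1.611, 2.250, 2.417, 2.538, 2.595]
  - [1.314, 1.740, 2.417, 3.240, 3.383, 3.416]
  - [1.397, 1.839, 2.538, 3.383, 4.410, 4.399]
  - [1.466, 1.905, 2.595, 3.416, 4.399, 6.760]
slowing_fraction: 0.20
n_per_arm: [200, 300, 400, 500, 600, 700]
duration_months: [18, 24, 36]
n_replicates: 200
seed: 1
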