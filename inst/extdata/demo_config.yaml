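# Demonstration pipeline configuration: a short session through every stage.
seed: 7
task:
  n_trials: 200
  p_high: 0.95
  rewards_per_block: 30
agent:
  alpha: 1.0
  beta: 2.0
  tau: 1.5
glm:
  method: ols
  runs: 2
stages: [simulate, synth, preprocess, rflr, trial_stats, glm, covariance]
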