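# Example experiment configuration for tplearn.
# Any key omitted falls back to the package default shown here.

observer:
  wf_start: 0.20        # internal Weber fraction before training
  wf_asymptote: 0.13    # asymptote for improving conditions
  tau_sessions: 1.5     # learning time constant (sessions)
  lapse_rate: 0.02      # probability of a random response

cohort:
  n_ei: 11              # empty-interval-trained observers
  n_fi: 12              # filled-interval-trained observers
  jitter_sd: 0.12       # log-normal inter-individual jitter on wf_start

staircase:
  initial_delta_fraction: 0.20
  coarse_step_fraction: 0.10
  fine_step_fraction: 0.05
  step_change_after_reversal: 3
  trials_per_block: 60

analysis:
  n_mad: 3
  mad_center: participant_median
  n_sd: 3
  max_flags: 1
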