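# Example run configuration for bpjoint::load_config().
# Omitted keys take their documented defaults; unknown keys are rejected.
seed: 20140101
generator:
  n: 3646
  sd_sbp: 16
  sd_dbp: 10
  rho: 0.7307
  replicates: 1
screening:
  p_threshold: 0.20
  vif_threshold: 10
inference:
  robust: false
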