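# Example run configuration: flat key = value, '#' starts a comment.
# Unset keys fall back to the published defaults.

# synthetic ODN pharmacology
AD_dose  = 100000      # copies; 1 uM at omega = 1e5
k_soff   = 0.02        # min^-1, slow (high-affinity) decoys
lambda_s = 0.004       # min^-1, nuclease degradation
k_s      = 0           # uM^-1 min^-1, no molecular stripping

# simulation settings
t_end    = 6000        # min
dt_out   = 0.5         # min
n_bins   = 15
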