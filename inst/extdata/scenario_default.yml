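# Default assessment scenario: diabetic population without social security,
# Mexico, annual cycles 2016-2032.
start_year: 2016
horizon_years: 16
control_fraction: 0.187
rate_policy_controlled: min
rate_policy_uncontrolled: max
n_sim: auto
error_bound: 10000
seed: 20160101
condition_on_survival: false
cohort_sizes_file: cohort_sizes.csv
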