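# Example ckdmicrosim config: flat key/value overrides of the base case.
# Any parameter name accepted by ckd_parameters() is a valid key.
initial_egfr: 76
cohort_size: 20000
seed: 42
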