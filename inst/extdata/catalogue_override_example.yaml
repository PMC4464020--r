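# Example indicator-bound override file for load_metric_catalogue().
# Only lower_bound / upper_bound of existing indicators may be changed.
delivery_outcome: {lower_bound: 90}
sex_ratio: {lower_bound: 0.85, upper_bound: 1.25}
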