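{"beta0":-3.03988616937876,"beta":1.16401636138766,"residual_sd":0.196136064068039,"n_points":87,"note":"synthetic: fitted on simulate_calibration_dataset(n = 100, seed = 20180821) with package defaults"}
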