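p_known,m1_fraction
0,0.048588
0.005,0.057396
0.01,0.066271
0.02,0.084425
0.03,0.101942
0.045,0.128715
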