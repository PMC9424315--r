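# NSN-to-SN transition: 40% obstacle anchoring and 1.8x activity at 12 h
activity: 0.55
transition_time_h: 12
anchored_fraction: 0.4
activity_multiplier: 1.8
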