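# SN-like state: 40% of obstacles anchored to the nucleolus from the start
activity: 1.0
anchored_fraction: 0.4
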