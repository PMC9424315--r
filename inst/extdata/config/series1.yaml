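# NSN-like state: obstacles dispersed, constant activity, 20 h horizon
activity: 0.55
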