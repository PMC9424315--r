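# NSN-stage control oocyte: dispersed chromatin-like obstacles
activity: 0.55
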