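# NSN-stage FMN2 knockout: SN activity 0.2 scaled by the 1.8 ratio
activity: 0.1111111111111111
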