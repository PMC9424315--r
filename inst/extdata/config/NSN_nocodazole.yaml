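# NSN stage with microtubules disrupted: SN activity 1.9 scaled by the
# 1.8 NSN-to-SN activity ratio
activity: 1.0555555555555556
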