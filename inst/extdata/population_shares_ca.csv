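region,population
CA-ON,38.3
CA-QC,23.2
CA-REST,38.5
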