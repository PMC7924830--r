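cell_size_km: 5.0
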