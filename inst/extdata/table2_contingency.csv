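color_class,nocturnal,variable,diurnal
pale,9,1,0
dark,0,13,3
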