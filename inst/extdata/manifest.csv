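file,checksum
table2_doses.csv,1011671302
table3_parameters.csv,0484059349
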