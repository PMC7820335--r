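rec1	recipient
line1	introgressed
don1	donor
out1	outgroup
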