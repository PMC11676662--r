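allele	frequency	frequency_unit
A*11	9.3	percent
B*08	7.7	percent
B*40	5	percent
B*47	0.6	percent
B*73	0.1	percent
DRB1*13	10.5	percent
DRB1*16	9.6	percent
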