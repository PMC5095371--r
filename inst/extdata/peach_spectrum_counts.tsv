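class	intraspecific	interspecific
A:T>G:C	14	16
G:C>A:T	53	86
A:T>T:A	12	11
A:T>C:G	5	8
G:C>T:A	11	19
G:C>C:G	1	4
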