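haplogroup	parent	variants
root		
HV0	root	16298C 72C 200G
V	HV0	4580A
U4c1	root	16179T 16356C 16512C 16519C 73G 189G 195C 499A
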