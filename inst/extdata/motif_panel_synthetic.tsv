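region	casOffset	threshold
C1	NA	0.45
C2	6	0.45
C3	NA	0.45
C4	4	0.45
C5	NA	0.45
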