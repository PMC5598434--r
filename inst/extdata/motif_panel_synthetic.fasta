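>C1_1
YFQFTQQYQPAC
>C1_2
YFEFTQQYQPAC
>C1_3
YFQFVQQYQPAC
>C2_1
CWNFTIHGLWPD
>C2_2
CWDFTIHGLWPD
>C2_3
CWNFTLHGLWPD
>C3_1
CWPDLTKSRHDW
>C3_2
CWPNLTKTRHDW
>C3_3
CWPDLTSSRHDW
>C4_1
WEIKHGTCCQFY
>C4_2
WPIKHGTCSQFY
>C4_3
WEIKHGSCCQFY
>C5_1
WGAFPNLTSWCY
>C5_2
WGAFPDLNSWCY
>C5_3
WGSFPNLTAWCY
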