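name	recognition	blunt_length	left_flank	right_flank
AlfI	GCANNNNNNTGC	32
AloI	GAACNNNNNNTCC	27
BaeI	ACNNNNGTAYC	28
BcgI	CGANNNNNNTGC	32
BplI	GAGNNNNNCTC	27
BsaXI	ACNNNNNCTCC	27
BslFI	GGGAC	21
Bsp24I	GACNNNNNNTGG	27
CspCI	CAANNNNNGTGG	33
FalI	AAGNNNNNCTT	27
HaeIV	GAYNNNNNRTC	27
PpiI	GAACNNNNNCTC	27
PsrI	GAACNNNNNNTAC	27
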