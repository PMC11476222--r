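class	hex	hexnac	neuac	sulfate	phosphate	requires_acyl	isomer_group	elution_note
Cer	0	0	0	0	0	TRUE		
CerP	0	0	0	0	1	TRUE		
Hex1Cer	1	0	0	0	0	TRUE		
Hex2Cer	2	0	0	0	0	TRUE		
Hex3Cer	3	0	0	0	0	TRUE		
GM3	2	0	1	0	0	TRUE		elutes early among gangliosides (single sialic acid)
GM2	2	1	1	0	0	TRUE		
GM1	3	1	1	0	0	TRUE	GM1a;GM1b	
GD3	2	0	2	0	0	TRUE		
GD2	2	1	2	0	0	TRUE		
GD1	3	1	2	0	0	TRUE	GD1a;GD1b	GD1a elutes before GD1b on ZIC-HILIC
GT3	2	0	3	0	0	TRUE		
GT2	2	1	3	0	0	TRUE		
GT1	3	1	3	0	0	TRUE	GT1a;GT1b;GT1c	
GQ1	3	1	4	0	0	TRUE	GQ1b;GQ1c	
GA2	2	1	0	0	0	TRUE		
GA1	3	1	0	0	0	TRUE		
ST	1	0	0	1	0	TRUE		
SPHP	0	0	0	0	1	FALSE		
CerG2GNAc1	2	1	0	0	0	TRUE		
CerG3GNAc2	3	2	0	0	0	TRUE		
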